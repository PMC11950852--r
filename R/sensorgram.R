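## Sensorgram forward model and 1:1 fitting, mirroring how SPR instruments
## report concentration-series traces.

#' Construct a sensorgram object
#'
#' @param concentrations analyte concentrations, M.
#' @param times time grid, s.
#' @param response response matrix (times x concentrations), RU.
#' @param assocEnd end of the association phase, s.
#' @param dissocEnd end of the dissociation phase, s.
#' @return a [Sensorgram-class] object.
#' @export
Sensorgram <- function(concentrations, times, response, assocEnd, dissocEnd) {
  new("Sensorgram", concentrations = concentrations, times = times,
      response = as.matrix(response), assocEnd = assocEnd,
      dissocEnd = dissocEnd)
}

setMethod("show", "Sensorgram", function(object) {
  cat(sprintf(
    "Sensorgram: %d concentrations (%.3g..%.3g M), %d time points, assoc end %g s\n",
    length(object@concentrations), min(object@concentrations),
    max(object@concentrations), length(object@times), object@assocEnd))
})

## Noiseless 1:1 forward model for one concentration over a time grid.
oneToOneResponse <- function(ka, kd, Rmax, conc, times, assocEnd) {
  KD <- kd / ka
  kobs <- ka * conc + kd
  Req <- Rmax * conc / (conc + KD)
  assoc <- times <= assocEnd
  r <- numeric(length(times))
  r[assoc] <- Req * (-expm1(-kobs * times[assoc]))
  Rend <- Req * (-expm1(-kobs * assocEnd))
  r[!assoc] <- Rend * exp(-kd * (times[!assoc] - assocEnd))
  r
}

#' Simulate a concentration-series sensorgram under the 1:1 model
#'
#' Association phase
#' \eqn{R(t) = R_{max} \frac{C}{C + K_D} (1 - e^{-(k_a C + k_d) t})},
#' dissociation phase \eqn{R(t) = R_{end} e^{-k_d (t - t_{assoc})}}, with
#' optional i.i.d. Gaussian noise.
#'
#' @param p a [KineticParams-class].
#' @param concentrations analyte concentration series, M.
#' @param Rmax saturating response, RU.
#' @param assocTime association-phase length, s.
#' @param dissocTime dissociation-phase length, s.
#' @param dt sampling interval, s.
#' @param noiseSd Gaussian noise standard deviation, RU.
#' @param seed RNG seed used when `noiseSd > 0`.
#' @return a [Sensorgram-class] object.
#' @examples
#' s <- simulateSensorgram(KineticParams(1e5, 5e-3), c(1e-8, 1e-7), Rmax = 100)
#' @export
simulateSensorgram <- function(p, concentrations, Rmax,
                               assocTime = 120, dissocTime = 300, dt = 1,
                               noiseSd = 0, seed = 1L) {
  stopifnot(is(p, "KineticParams"), all(concentrations > 0), Rmax > 0)
  times <- seq(0, assocTime + dissocTime, by = dt)
  resp <- vapply(concentrations, function(C)
    oneToOneResponse(p@ka, p@kd, Rmax, C, times, assocTime),
    numeric(length(times)))
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    resp <- resp + matrix(stats::rnorm(length(resp), 0, noiseSd),
                          nrow = nrow(resp))
  }
  Sensorgram(concentrations, times, resp, assocTime, assocTime + dissocTime)
}

#' Fit a 1:1 binding model to a sensorgram
#'
#' Global nonlinear least squares over (k_a, k_d, Rmax) against the two-phase
#' 1:1 forward model, all concentrations fitted jointly. Parameters are
#' optimised on the log scale to enforce positivity. Initialisation is
#' two-stage: k_d from a log-linear regression on the dissociation tail of the
#' highest concentration, then K_D (hence k_a) from inverting the equilibrium
#' plateau.
#'
#' Non-convergence and degenerate (flat) inputs are reported through the
#' `converged`/`degenerate` flags rather than as errors.
#'
#' @param s a [Sensorgram-class] with at least two concentrations.
#' @return list with `params` ([KineticParams-class] or `NULL`), `Rmax`,
#'   `residualNorm`, `converged`, `degenerate`, and the `fit` object.
#' @examples
#' s <- simulateSensorgram(KineticParams(2e5, 1e-2), c(3e-8, 1e-7, 3e-7),
#'                         Rmax = 80)
#' fitOneToOne(s)$params
#' @export
fitOneToOne <- function(s) {
  stopifnot(is(s, "Sensorgram"))
  if (length(s@concentrations) < 2L)
    stop("at least two concentrations are required")
  times <- s@times
  flat <- max(abs(s@response)) < 1e-9 ||
    stats::sd(as.vector(s@response)) < 1e-9
  if (flat)
    return(list(params = NULL, Rmax = NA_real_, residualNorm = NA_real_,
                converged = FALSE, degenerate = TRUE, fit = NULL))

  hi <- which.max(s@concentrations)
  dis <- times > s@assocEnd
  yd <- s@response[dis, hi]
  td <- times[dis] - s@assocEnd
  pos <- yd > max(yd, na.rm = TRUE) * 1e-3
  kd0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(yd[pos]) ~ td[pos]))[2L]
    max(-sl, 1e-8)
  } else 1e-8
  Rmax0 <- max(s@response) * 1.05
  Rend <- max(s@response[times <= s@assocEnd, hi])
  frac <- min(Rend / Rmax0, 0.999)
  KD0 <- s@concentrations[hi] * (1 - frac) / frac
  ka0 <- kd0 / max(KD0, 1e-15)

  long <- data.frame(
    t = rep(times, length(s@concentrations)),
    conc = rep(s@concentrations, each = length(times)),
    y = as.vector(s@response))
  model <- function(lka, lkd, lRmax, t, conc) {
    kaV <- exp(lka); kdV <- exp(lkd); RmaxV <- exp(lRmax)
    unlist(lapply(unique(conc), function(C)
      oneToOneResponse(kaV, kdV, RmaxV, C, times, s@assocEnd)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ model(lka, lkd, lRmax, t, conc),
      data = long,
      start = list(lka = log(ka0), lkd = log(kd0), lRmax = log(Rmax0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(params = NULL, Rmax = NA_real_, residualNorm = NA_real_,
                converged = FALSE, degenerate = FALSE, fit = NULL))
  cf <- stats::coef(fit)
  list(params = KineticParams(ka = exp(cf[["lka"]]), kd = exp(cf[["lkd"]])),
       Rmax = exp(cf[["lRmax"]]),
       residualNorm = sqrt(sum(stats::residuals(fit)^2)),
       converged = fit$convInfo$isConv %||% TRUE,
       degenerate = FALSE,
       fit = fit)
}

#' Write a sensorgram as a delimited table with a small header
#'
#' @param s a [Sensorgram-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSensorgram <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# concentrations_M: ", paste(format(s@concentrations, digits = 12),
                                         collapse = ",")),
    paste0("# assoc_end_s: ", format(s@assocEnd, digits = 12)),
    paste0("# dissoc_end_s: ", format(s@dissocEnd, digits = 12))), con)
  df <- data.frame(time = s@times, s@response)
  names(df) <- c("time", paste0("conc", seq_along(s@concentrations)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sensorgram written by [writeSensorgram()]
#'
#' @param path input file path.
#' @return a [Sensorgram-class].
#' @export
readSensorgram <- function(path) {
  lines <- readLines(path, n = 3L)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (!length(ln)) stop("missing sensorgram header field: ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln), ",")[[1L]])
  }
  concs <- getv("concentrations_M")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  Sensorgram(concs, df$time, as.matrix(df[, -1L, drop = FALSE]),
             getv("assoc_end_s"), getv("dissoc_end_s"))
}
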