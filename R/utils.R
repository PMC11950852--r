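## Internal numerics shared across modules. Molecule counts are stored as
## doubles throughout: campaign budgets reach 1e14, far beyond integer range.

#' Multinomial draw for counts beyond integer range
#'
#' `stats::rmultinom()` rejects sizes above `.Machine$integer.max`; selection
#' campaigns resample pools of up to ~1e14 molecules. This draws the same
#' distribution through the conditional-binomial decomposition, which only
#' requires `rbinom()` (double-size capable).
#'
#' @param size total number of draws (nonnegative double).
#' @param prob nonnegative weights, not necessarily normalised.
#' @return numeric vector of counts summing to `size`.
#' @keywords internal
rmultinomLarge <- function(size, prob) {
  stopifnot(size >= 0, all(prob >= 0), length(prob) >= 1)
  k <- length(prob)
  out <- numeric(k)
  if (size == 0 || sum(prob) == 0) return(out)
  rem <- size
  psum <- sum(prob)
  for (i in seq_len(k - 1L)) {
    if (rem <= 0 || psum <= 0) break
    p <- prob[i] / psum
    out[i] <- stats::rbinom(1L, rem, min(1, max(0, p)))
    rem <- rem - out[i]
    psum <- psum - prob[i]
  }
  out[k] <- max(rem, 0)
  out
}

#' Pairwise Hamming distances between equal-length strings
#'
#' @param seqs character vector of equal-length sequences.
#' @return integer matrix of pairwise mismatch counts.
#' @keywords internal
hammingMatrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("all sequences must have equal length for Hamming distances")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  if (n == 1L) return(d)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    di <- as.integer(colSums(t(m[rest, , drop = FALSE]) != m[i, ]))
    d[i, rest] <- di
    d[rest, i] <- di
  }
  d
}

## Union-find over n items; merge pairs given as two-column index matrix.
## Deterministic and invariant to input order (components are sets).
unionFindComponents <- function(n, pairs) {
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[r, 1L])
      b <- findRoot(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}

## Half-up rounding at a given number of decimal digits; used when comparing
## derived K_D values to printed nM precision (R's round() is half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Derive a deterministic sequence of child seeds from one root seed, so each
## simulator stage consumes an independent, reproducible stream.
childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
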