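## 1:1 Langmuir binding-kinetics core: K_D arithmetic, association dynamics,
## wash survival, log-scale family averaging.

#' Construct kinetic parameters
#'
#' @param ka association rate constant, M^-1 s^-1.
#' @param kd dissociation rate constant, s^-1.
#' @return a [KineticParams-class] object.
#' @examples
#' KineticParams(ka = 5.9e5, kd = 4.2e-3)
#' @export
KineticParams <- function(ka, kd) new("KineticParams", ka = ka, kd = kd)

#' @rdname accessors
#' @export
setMethod("ka", "KineticParams", function(object) object@ka)
#' @rdname accessors
#' @export
setMethod("kd", "KineticParams", function(object) object@kd)
#' @rdname accessors
#' @export
setMethod("ka", "FamilyKinetics", function(object) object@kaAvg)
#' @rdname accessors
#' @export
setMethod("kd", "FamilyKinetics", function(object) object@kdAvg)

#' @rdname dissociationConstant
#' @export
setMethod("dissociationConstant", "KineticParams",
          function(object) object@kd / object@ka)
#' @rdname dissociationConstant
#' @export
setMethod("dissociationConstant", "FamilyKinetics",
          function(object) object@KDAvg)

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: ka = %.3g /M/s, kd = %.3g /s, KD = %.3g M\n",
              object@ka, object@kd, dissociationConstant(object)))
})

setMethod("show", "FamilyKinetics", function(object) {
  cat(sprintf(
    "FamilyKinetics (n = %d): ka_avg = %.3g /M/s, kd_avg = %.3g /s, KD_avg = %.3g M\n",
    object@n, object@kaAvg, object@kdAvg, object@KDAvg))
})

#' Log-scale (geometric) family-average kinetics
#'
#' Family averages are computed in logarithmic scale: the geometric means of
#' the member k_a and k_d. The geometric mean of the member K_D values then
#' equals `kdAvg / kaAvg` exactly.
#'
#' @param members list of [KineticParams-class] objects (at least one).
#' @return a [FamilyKinetics-class] object.
#' @examples
#' familyLogAverage(list(KineticParams(1e5, 1e-3), KineticParams(1e5, 1e-1)))
#' @export
familyLogAverage <- function(members) {
  if (!length(members)) stop("family must have at least one member")
  if (!all(vapply(members, is, logical(1), "KineticParams")))
    stop("members must be KineticParams objects")
  lka <- mean(vapply(members, function(m) log10(m@ka), numeric(1)))
  lkd <- mean(vapply(members, function(m) log10(m@kd), numeric(1)))
  new("FamilyKinetics", kaAvg = 10^lka, kdAvg = 10^lkd,
      KDAvg = 10^(lkd - lka), n = length(members))
}

#' Fraction of peptide bound to target after an incubation
#'
#' Closed-form solution of the pseudo-first-order 1:1 Langmuir model
#' \eqn{dB/dt = k_a C (1 - B) - k_d B} starting from B(0) = 0:
#' \deqn{f(t) = \frac{k_a C}{k_a C + k_d}\left(1 - e^{-(k_a C + k_d) t}\right)}
#' Monotone nondecreasing in both t and C, with equilibrium limit
#' \eqn{C / (C + K_D)}.
#'
#' @param p a [KineticParams-class].
#' @param targetConc free target concentration, M (held constant).
#' @param t incubation time, s (vectorised).
#' @return bound fraction in \[0, 1\].
#' @examples
#' fractionBound(KineticParams(5.9e5, 4.2e-3), 1e-7, 1800)
#' @export
fractionBound <- function(p, targetConc, t) {
  stopifnot(is(p, "KineticParams"))
  if (any(targetConc < 0) || any(t < 0))
    stop("targetConc and t must be nonnegative")
  .fractionBound(p@ka, p@kd, targetConc, t)
}

## vectorised internal form used by the selection simulator
.fractionBound <- function(ka, kd, C, t) {
  kobs <- ka * C + kd
  (ka * C / kobs) * (-expm1(-kobs * t))
}

#' Survival of a bound complex through bead washes
#'
#' Probability that a 1:1 complex with dissociation rate k_d survives
#' `nWashes` washes of `tWash` seconds each, with rebinding during washes
#' neglected (no free target in the wash buffer):
#' \eqn{\exp(-k_d \cdot n \cdot t)}.
#'
#' @param kd dissociation rate, s^-1 (vectorised).
#' @param nWashes number of washes (nonnegative integer).
#' @param tWash single-wash duration, s.
#' @return retained fraction in \[0, 1\].
#' @examples
#' washRetention(4.2e-3, 3, 60) # exp(-0.756)
#' @export
washRetention <- function(kd, nWashes, tWash) {
  if (any(kd < 0) || nWashes < 0 || tWash < 0)
    stop("kd, nWashes and tWash must be nonnegative")
  exp(-kd * nWashes * tWash)
}
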