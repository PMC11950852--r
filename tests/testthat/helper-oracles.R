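# Shared helpers for the test suite: independent oracles and small fixtures.

# Rand index between two partitions given as label vectors.
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  sameA <- a[pairs[1, ]] == a[pairs[2, ]]
  sameB <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(sameA == sameB)
}

# Independent ODE oracle for the bound fraction: numerical integration of
# dB/dt = ka*C*(1-B) - kd*B.
odeFractionBound <- function(ka, kd, C, tEnd) {
  sol <- deSolve::ode(
    y = c(B = 0), times = c(0, tEnd),
    func = function(t, y, parms) list(ka * C * (1 - y[1]) - kd * y[1]),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(sol[nrow(sol), "B"])
}

# Two-species state (plus optional background) for simulator tests.
twoSpeciesState <- function(ka1, kd1, ka2, kd2, count = 1e6,
                            stickiness = 0, withBackground = FALSE) {
  species <- data.frame(
    id = c("s1", "s2"), peptide = c("AAAAA", "WWWWW"),
    dna = NA_character_, ka = c(ka1, ka2), kd = c(kd1, kd2),
    stickiness = stickiness, family = NA_character_,
    count = rep(count, 2), stringsAsFactors = FALSE)
  background <- if (withBackground)
    data.frame(id = "bin001", ka = 100, kd = 1, stickiness = 2e-3,
               count = 1e9, stringsAsFactors = FALSE)
  else emptyBackgroundTable()
  LibraryState(species, background)
}

# Small fixture spec for fast cross-module tests.
smallFixtureSpec <- function(rounds = 3L) defaultFixtureSpec(rounds = rounds)
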