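## Stochastic round-by-round simulator of an affinity-selection campaign.
## All stage operations act on aggregated per-species copy numbers, so
## campaigns at 1e12-1e14 molecule budgets run at desk scale.

#' Construct an empty or populated library state
#'
#' @param species species data.frame (see [LibraryState-class]); a zero-row
#'   default is supplied.
#' @param background background-bin data.frame.
#' @return a [LibraryState-class] object.
#' @export
LibraryState <- function(species = emptySpeciesTable(),
                         background = emptyBackgroundTable()) {
  new("LibraryState", species = species, background = background)
}

#' @rdname LibraryState
#' @export
emptySpeciesTable <- function() {
  data.frame(id = character(), peptide = character(), dna = character(),
             ka = numeric(), kd = numeric(), stickiness = numeric(),
             family = character(), count = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname LibraryState
#' @export
emptyBackgroundTable <- function() {
  data.frame(id = character(), ka = numeric(), kd = numeric(),
             stickiness = numeric(), count = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("speciesTable", "LibraryState", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("backgroundTable", "LibraryState", function(object) object@background)
#' @rdname accessors
#' @export
setMethod("totalMolecules", "LibraryState", function(object)
  sum(object@species$count) + sum(object@background$count))

setMethod("show", "LibraryState", function(object) {
  cat(sprintf(
    "LibraryState: %d tracked species (%.4g molecules), %d background bins (%.4g molecules)\n",
    nrow(object@species), sum(object@species$count),
    nrow(object@background), sum(object@background$count)))
})

#' Construct a selection-campaign configuration
#'
#' Defaults model the reference protocol: 100 nM target, 30 min incubation,
#' one negative pass, three 12 s washes, capture efficiency 2e-3 (end-to-end
#' recovery of a bound molecule through elution and PCR rescue), nonspecific
#' carryover 5e-3, PCR at 1e-4 mutations/base/cycle for 15 cycles, and a
#' 1.8e12-molecule translation budget. With these values a background-
#' dominated round recovers ~1e-5 of its input, inside the 0.0005-0.002%
#' window typical of early selection rounds; see the package vignette for the
#' calibration argument.
#'
#' @param targetConc target concentration, M.
#' @param incubationTime incubation, s.
#' @param nWashes washes per round.
#' @param tWash seconds per wash.
#' @param captureEfficiency end-to-end bound-molecule recovery probability.
#' @param nonspecificCarryover carryover multiplier on species stickiness.
#' @param negativeRounds negative-selection passes.
#' @param pcrMutationRate per-base per-cycle mutation probability.
#' @param pcrCycles PCR cycles per round.
#' @param ribosomeBudget molecules translated per round.
#' @param readDepth sequencing reads per round.
#' @param seed root RNG seed.
#' @return a [SelectionConfig-class] object.
#' @export
SelectionConfig <- function(targetConc = 1e-7,
                            incubationTime = 1800,
                            nWashes = 3L,
                            tWash = 12,
                            captureEfficiency = 2e-3,
                            nonspecificCarryover = 5e-3,
                            negativeRounds = 1L,
                            pcrMutationRate = 1e-4,
                            pcrCycles = 15L,
                            ribosomeBudget = 1.8e12,
                            readDepth = 1e5,
                            seed = 1L) {
  new("SelectionConfig", targetConc = targetConc,
      incubationTime = incubationTime, nWashes = as.integer(nWashes),
      tWash = tWash, captureEfficiency = captureEfficiency,
      nonspecificCarryover = nonspecificCarryover,
      negativeRounds = as.integer(negativeRounds),
      pcrMutationRate = pcrMutationRate, pcrCycles = as.integer(pcrCycles),
      ribosomeBudget = ribosomeBudget, readDepth = readDepth,
      seed = as.integer(seed))
}

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf(
    paste0("SelectionConfig: target %.3g M, incubation %g s, %d x %g s washes,\n",
           "  capture %.3g, carryover %.3g, PCR %.1g/base/cycle x %d, budget %.3g\n"),
    object@targetConc, object@incubationTime, object@nWashes, object@tWash,
    object@captureEfficiency, object@nonspecificCarryover,
    object@pcrMutationRate, object@pcrCycles, object@ribosomeBudget))
})

#' @rdname accessors
#' @export
setMethod("recoveryRate", "RoundResult", function(object) object@recoveryRate)
#' @rdname accessors
#' @export
setMethod("roundResults", "CampaignResult", function(object) object@rounds)
#' @rdname accessors
#' @export
setMethod("readTables", "CampaignResult", function(object) object@readTables)
#' @rdname accessors
#' @export
setMethod("recoveryRate", "CampaignResult", function(object)
  vapply(object@rounds, slot, numeric(1), "recoveryRate"))

setMethod("show", "RoundResult", function(object) {
  cat(sprintf("RoundResult %d: %.4g of %.4g molecules recovered (%.3g%%)\n",
              object@roundIndex, object@recoveredTotal, object@inputTotal,
              100 * object@recoveryRate))
})

setMethod("show", "CampaignResult", function(object) {
  cat(sprintf("CampaignResult '%s': %d rounds (seed %d)\n", object@library,
              length(object@rounds), object@seed))
  print(roundSummary(object), digits = 4)
})

#' @rdname roundSummary
#' @export
setMethod("roundSummary", "CampaignResult", function(object) {
  data.frame(
    round = vapply(object@rounds, slot, integer(1), "roundIndex"),
    input = vapply(object@rounds, slot, numeric(1), "inputTotal"),
    recovered = vapply(object@rounds, slot, numeric(1), "recoveredTotal"),
    recoveryRate = vapply(object@rounds, slot, numeric(1), "recoveryRate"))
})

#' Per-copy survival probability through one positive-selection round
#'
#' The round's model of the selection pressure: a molecule survives either
#' specifically -- it associates during the incubation
#' ([fractionBound()]), stays bound through the washes ([washRetention()]),
#' and is recovered end-to-end with the capture efficiency -- or
#' nonspecifically, sticking to the beads and being carried into the eluate:
#' \deqn{p = \epsilon_c \, f_{bound} \, w_{ret} + s \cdot c}
#'
#' @param ka,kd kinetic rates (vectorised).
#' @param stickiness nonspecific bead-binding probability (vectorised).
#' @param config a [SelectionConfig-class].
#' @return survival probability per molecule, clamped to \[0, 1\].
#' @export
survivalProbability <- function(ka, kd, stickiness, config) {
  fb <- .fractionBound(ka, kd, config@targetConc, config@incubationTime)
  w <- exp(-kd * config@nWashes * config@tWash)
  p <- config@captureEfficiency * fb * w +
    stickiness * config@nonspecificCarryover
  pmin(pmax(p, 0), 1)
}

#' Downsample a library to the translation budget
#'
#' If the pool holds no more molecules than the ribosome budget every molecule
#' is translated (identity); otherwise the pool is downsampled to the budget
#' by multinomial resampling (the multinomial approximation to multivariate
#' hypergeometric sampling at these scales).
#'
#' @param state a [LibraryState-class].
#' @param budget ribosome budget, molecules.
#' @param seed RNG seed.
#' @return downsampled [LibraryState-class].
#' @export
translationSampling <- function(state, budget, seed = 1L) {
  stopifnot(is(state, "LibraryState"), budget > 0)
  total <- totalMolecules(state)
  if (total <= budget) return(state)
  set.seed(as.integer(seed))
  ns <- nrow(state@species)
  cnt <- c(state@species$count, state@background$count)
  newCnt <- rmultinomLarge(budget, cnt)
  state@species$count <- newCnt[seq_len(ns)]
  state@background$count <- newCnt[ns + seq_len(nrow(state@background))]
  state
}

#' Apply negative selection against naked/tag-only beads
#'
#' Each copy of a species is removed with its stickiness probability per
#' negative pass (removal is what negative selection is for: sticky molecules
#' bind the naked beads and are discarded with them).
#'
#' @param state a [LibraryState-class].
#' @param config a [SelectionConfig-class].
#' @param seed RNG seed.
#' @return cleared [LibraryState-class].
#' @export
applyNegativeSelection <- function(state, config, seed = 1L) {
  stopifnot(is(state, "LibraryState"), is(config, "SelectionConfig"))
  if (config@negativeRounds == 0L) return(state)
  set.seed(as.integer(seed))
  keepS <- (1 - state@species$stickiness)^config@negativeRounds
  keepB <- (1 - state@background$stickiness)^config@negativeRounds
  if (nrow(state@species))
    state@species$count <- stats::rbinom(nrow(state@species),
                                         state@species$count, keepS)
  if (nrow(state@background))
    state@background$count <- stats::rbinom(nrow(state@background),
                                            state@background$count, keepB)
  state
}

#' Apply kinetics-governed positive selection
#'
#' Draws each species' recovered copies binomially at the per-copy
#' [survivalProbability()] and reports the round recovery rate (recovered
#' over input molecules, the cDNA-recovery ratio a selection campaign tracks).
#'
#' @param state a [LibraryState-class].
#' @param config a [SelectionConfig-class].
#' @param seed RNG seed.
#' @param roundIndex round number recorded on the result.
#' @return a [RoundResult-class].
#' @export
applyPositiveSelection <- function(state, config, seed = 1L, roundIndex = 1L) {
  stopifnot(is(state, "LibraryState"), is(config, "SelectionConfig"))
  input <- totalMolecules(state)
  if (input == 0) {
    return(new("RoundResult", roundIndex = as.integer(roundIndex),
               inputTotal = 0, recoveredTotal = 0, recoveryRate = 0,
               postState = state, empty = TRUE))
  }
  set.seed(as.integer(seed))
  if (nrow(state@species)) {
    pS <- survivalProbability(state@species$ka, state@species$kd,
                              state@species$stickiness, config)
    state@species$count <- stats::rbinom(nrow(state@species),
                                         state@species$count, pS)
  }
  if (nrow(state@background)) {
    pB <- survivalProbability(state@background$ka, state@background$kd,
                              state@background$stickiness, config)
    state@background$count <- stats::rbinom(nrow(state@background),
                                            state@background$count, pB)
  }
  recovered <- totalMolecules(state)
  new("RoundResult", roundIndex = as.integer(roundIndex), inputTotal = input,
      recoveredTotal = recovered, recoveryRate = recovered / input,
      postState = state, empty = FALSE)
}

## Transition (3x) vs transversion (1x each) substitution kernel.
.mutationTargets <- function(base) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  others <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b)
    setdiff(c("A", "C", "G", "T"), c(b, transitions[[b]])))
  list(ts = transitions[[base]], tv = others[[base]])
}

#' Apply a point mutation to a DNA sequence
#'
#' Deterministic helper used by the PCR stage (exposed for testing mutation
#' consequences, e.g. GAG -> AAG replacing Glu with Lys).
#'
#' @param dna DNA string.
#' @param position 1-based base position.
#' @param base replacement base.
#' @return mutated DNA string.
#' @examples
#' mutateDna("GAG", 1, "A") # AAG: E -> K
#' @export
mutateDna <- function(dna, position, base) {
  stopifnot(position >= 1, position <= nchar(dna), base %in% c("A", "C", "G", "T"))
  substr(dna, position, position) <- base
  dna
}

## Draw one random single-base mutation of `dna` with ts:tv = 3:1.
.randomPointMutation <- function(dna) {
  pos <- sample.int(nchar(dna), 1L)
  from <- substr(dna, pos, pos)
  tg <- .mutationTargets(from)
  to <- if (stats::runif(1) < 0.75) tg$ts else sample(tg$tv, 1L)
  mutateDna(dna, pos, to)
}

#' PCR amplification with point mutation
#'
#' Rescales the pool to `targetTotal` molecules by multinomial resampling
#' (amplification bias beyond sampling noise is not modelled), then lets each
#' copied molecule of a tracked species mutate with probability
#' \eqn{1 - (1 - \mu)^{L \cdot cycles}}. Mutant molecules of a species are
#' assigned to at most `maxMutantLineages` distinct single-base variants per
#' round (transition:transversion 3:1); a variant whose DNA matches an
#' existing species merges into it, otherwise it becomes a new species whose
#' kinetics are the parent's jittered on the log scale. Variants acquiring a
#' stop codon are retained as translation-dead species with nonbinder
#' kinetics. Background bins model the nonbinding bulk and are resampled but
#' not mutated.
#'
#' @param state a [LibraryState-class].
#' @param config a [SelectionConfig-class].
#' @param targetTotal molecule count after amplification.
#' @param seed RNG seed.
#' @param maxMutantLineages distinct mutant variants created per species per
#'   round.
#' @param kineticJitter log10 sd applied to mutant kinetics.
#' @param minLineageSize smallest mutant molecule mass split into its own
#'   lineage; smaller mutant mass stays with the parent species (a vanishing
#'   bias at campaign budgets that keeps the species table bounded).
#' @return amplified [LibraryState-class]; species driven extinct by the
#'   preceding selection are dropped from the table.
#' @export
pcrAmplify <- function(state, config, targetTotal, seed = 1L,
                       maxMutantLineages = 2L, kineticJitter = 0.2,
                       minLineageSize = max(100, 1e-6 * targetTotal)) {
  stopifnot(is(state, "LibraryState"), targetTotal > 0)
  total <- totalMolecules(state)
  if (total == 0) return(state)
  set.seed(as.integer(seed))
  state@species <- state@species[state@species$count > 0, , drop = FALSE]
  ns <- nrow(state@species)
  cnt <- c(state@species$count, state@background$count)
  newCnt <- rmultinomLarge(targetTotal, cnt)
  state@species$count <- newCnt[seq_len(ns)]
  state@background$count <- newCnt[ns + seq_len(nrow(state@background))]

  mu <- config@pcrMutationRate
  if (mu > 0 && ns > 0) {
    sp <- state@species
    mutable <- !is.na(sp$dna) & nchar(sp$dna) > 0 & sp$count > 0
    pMut <- ifelse(mutable,
                   -expm1(nchar(sp$dna) * config@pcrCycles * log1p(-mu)), 0)
    nMutAll <- stats::rbinom(ns, ifelse(mutable, sp$count, 0), pMut)
    newRows <- list()
    for (i in which(nMutAll >= max(1, minLineageSize))) {
      nMut <- nMutAll[i]
      k <- min(maxMutantLineages, nMut)
      lineages <- vapply(seq_len(k), function(j) .randomPointMutation(sp$dna[i]),
                         character(1))
      shares <- rmultinomLarge(nMut, rep(1, k))
      sp$count[i] <- sp$count[i] - nMut
      for (j in seq_len(k)) {
        if (shares[j] <= 0) next
        hit <- which(sp$dna == lineages[j])
        if (length(hit)) {
          sp$count[hit[1L]] <- sp$count[hit[1L]] + shares[j]
          next
        }
        prior <- which(vapply(newRows, function(r) r$dna == lineages[j],
                              logical(1)))
        if (length(prior)) {
          newRows[[prior[1L]]]$count <- newRows[[prior[1L]]]$count + shares[j]
          next
        }
        ## a mutation can destroy the architecture itself (e.g. hit the
        ## initiator AUG): such molecules no longer translate at all
        tr <- tryCatch(translateDisplayConstruct(lineages[j]),
                       error = function(e) NULL)
        dead <- is.null(tr) || !tr$valid
        jit <- 10^stats::rnorm(2L, 0, kineticJitter)
        newRows[[length(newRows) + 1L]] <- data.frame(
          id = paste0(sp$id[i], ".m", length(newRows) + 1L, "r", seed %% 1000L),
          peptide = if (dead) NA_character_ else tr$randomRegion,
          dna = lineages[j],
          ka = if (dead) 1 else sp$ka[i] * jit[1L],
          kd = if (dead) 10 else sp$kd[i] * jit[2L],
          stickiness = sp$stickiness[i],
          family = sp$family[i],
          count = shares[j],
          stringsAsFactors = FALSE)
      }
    }
    if (length(newRows)) sp <- rbind(sp, do.call(rbind, newRows))
    state@species <- sp
  }
  validObject(state)
  state
}

#' Run a full multi-round selection campaign
#'
#' Iterates translation sampling, negative selection, positive selection, read
#' sampling of the recovered pool, and PCR re-amplification, for `nRounds`
#' rounds. All randomness derives from the root seed through per-stage child
#' seeds, so identical seeds give bit-identical campaigns.
#'
#' @param initial starting [LibraryState-class] (the round-1 translated pool).
#' @param config a [SelectionConfig-class].
#' @param nRounds number of rounds (default 7).
#' @param library library label recorded on outputs.
#' @param seed root seed; defaults to `config@seed`.
#' @param budgets optional per-round translation budgets (recycled); defaults
#'   to `config@ribosomeBudget`.
#' @return a [CampaignResult-class].
#' @examples
#' spec <- defaultFixtureSpec(rounds = 3L)
#' lib <- generatePlantedLibrary(spec, "E6", seed = 1)
#' res <- runCampaign(lib$state, SelectionConfig(), nRounds = 3, seed = 1)
#' roundSummary(res)
#' @export
runCampaign <- function(initial, config, nRounds = 7L, library = "lib",
                        seed = config@seed, budgets = NULL) {
  stopifnot(is(initial, "LibraryState"), is(config, "SelectionConfig"),
            nRounds >= 1L)
  budgets <- rep(budgets %||% config@ribosomeBudget, length.out = nRounds + 1L)
  seeds <- matrix(childSeeds(seed, nRounds * 5L), nrow = nRounds)
  state <- initial
  rounds <- vector("list", nRounds)
  tables <- vector("list", nRounds)
  for (r in seq_len(nRounds)) {
    state <- translationSampling(state, budgets[r], seed = seeds[r, 1L])
    state <- applyNegativeSelection(state, config, seed = seeds[r, 2L])
    rr <- applyPositiveSelection(state, config, seed = seeds[r, 3L],
                                 roundIndex = r)
    rounds[[r]] <- rr
    tables[[r]] <- if (!rr@empty && totalMolecules(rr@postState) > 0)
      sampleReadCounts(rr@postState, config@readDepth, seed = seeds[r, 4L],
                       library = library, round = r)
    else new("ReadCountTable", library = library, round = as.integer(r),
             counts = numeric(), isBackground = logical(),
             metadata = list(empty = TRUE))
    state <- if (rr@empty || totalMolecules(rr@postState) == 0) rr@postState
    else pcrAmplify(rr@postState, config, budgets[r + 1L],
                    seed = seeds[r, 5L])
  }
  new("CampaignResult", library = library, rounds = rounds,
      readTables = tables, config = config, seed = as.integer(seed))
}
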