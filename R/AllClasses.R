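## S4 class definitions for the whole package. Validity methods enforce the
## model invariants; constructors with sensible defaults live next to each
## module's operations.

#' NNK display-library construct architecture
#'
#' Describes the fixed architecture of the displayed open reading frame:
#' an initiator codon reprogrammed to N-chloroacetyl-L-tyrosine (rendered as a
#' distinguishable single-letter token), a run of NNK degenerate codons, a
#' fixed downstream Cys codon (UGU) used for thioether macrocyclisation, and
#' the C-terminal linker peptide.
#'
#' @slot randomCodonCount number of NNK codons in the random region.
#' @slot initiatorSymbol single-character token standing for the acylated
#'   initiator tyrosine in peptide strings.
#' @slot fixedCys whether the construct carries the fixed downstream Cys codon.
#' @slot linkerPeptide residue string of the linker (default `"SGGLTN"`).
#' @slot linkerDna DNA codons encoding the linker.
#' @slot degenerateAlphabet the 32 NNK codons (DNA alphabet, T-based).
#' @exportClass LibraryDesign
setClass("LibraryDesign",
  representation(
    randomCodonCount = "numeric",
    initiatorSymbol = "character",
    fixedCys = "logical",
    linkerPeptide = "character",
    linkerDna = "character",
    degenerateAlphabet = "character"
  )
)

setValidity("LibraryDesign", function(object) {
  msg <- character()
  if (length(object@randomCodonCount) != 1L || object@randomCodonCount < 0 ||
      object@randomCodonCount != floor(object@randomCodonCount))
    msg <- c(msg, "randomCodonCount must be a single nonnegative integer")
  if (nchar(object@initiatorSymbol) != 1L)
    msg <- c(msg, "initiatorSymbol must be a single character")
  if (length(object@degenerateAlphabet) != 32L ||
      anyDuplicated(object@degenerateAlphabet) ||
      !all(grepl("^[ACGT][ACGT][GT]$", object@degenerateAlphabet)))
    msg <- c(msg, "degenerateAlphabet must be the 32 distinct NNK codons (N in ACGT, K in GT)")
  if (nchar(object@linkerDna) != 3L * nchar(object@linkerPeptide))
    msg <- c(msg, "linkerDna must contain one codon per linker residue")
  if (length(msg)) msg else TRUE
})

#' A diversity-scale subset of the mother NNK library
#'
#' @slot name subset label (e.g. `"E14"`).
#' @slot estimatedDiversity number of unique sequences (stored verbatim when
#'   measured; diversities above 2^53 are represented as doubles).
#' @slot parent label of the parent subset, or `NA` for a mother library.
#' @slot dilutionFactor dilution applied when deriving from the parent
#'   (1 for a mother library).
#' @slot group sampling-lineage identifier.
#' @exportClass LibrarySubset
setClass("LibrarySubset",
  representation(
    name = "character",
    estimatedDiversity = "numeric",
    parent = "character",
    dilutionFactor = "numeric",
    group = "character"
  )
)

setValidity("LibrarySubset", function(object) {
  msg <- character()
  if (object@estimatedDiversity <= 0)
    msg <- c(msg, "estimatedDiversity must be positive")
  if (!is.na(object@parent) && object@dilutionFactor <= 1)
    msg <- c(msg, "derived subsets must have dilutionFactor > 1")
  if (object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' In vitro translation budget
#'
#' Volume and ribosome concentration of a translation reaction. Under the
#' monosome assumption each ribosome yields at most one peptide-mRNA fusion,
#' so the ribosome count is the molecule budget of a selection round.
#'
#' @slot volume reaction volume in microlitres.
#' @slot ribosomeConc ribosome concentration in pmol/µL (default 1.2).
#' @exportClass TranslationBudget
setClass("TranslationBudget",
  representation(volume = "numeric", ribosomeConc = "numeric")
)

setValidity("TranslationBudget", function(object) {
  msg <- character()
  if (object@volume < 0) msg <- c(msg, "volume must be nonnegative")
  if (object@ribosomeConc <= 0) msg <- c(msg, "ribosomeConc must be positive")
  if (length(msg)) msg else TRUE
})

#' 1:1 binding kinetic parameters
#'
#' Association rate \eqn{k_a} (M^-1 s^-1) and dissociation rate \eqn{k_d}
#' (s^-1) of a 1:1 Langmuir interaction; the equilibrium dissociation constant
#' is the derived quantity \eqn{K_D = k_d / k_a}.
#'
#' @slot ka association rate constant, M^-1 s^-1.
#' @slot kd dissociation rate constant, s^-1.
#' @exportClass KineticParams
setClass("KineticParams", representation(ka = "numeric", kd = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- character()
  if (length(object@ka) != 1L || !is.finite(object@ka) || object@ka <= 0)
    msg <- c(msg, "ka must be a single positive finite number")
  if (length(object@kd) != 1L || !is.finite(object@kd) || object@kd <= 0)
    msg <- c(msg, "kd must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Log-scale average kinetics of a peptide family
#'
#' Geometric (log-scale) means of the member rate constants. Because the
#' averages are geometric, \eqn{K_{D,avg} = k_{d,avg} / k_{a,avg}} holds as an
#' algebraic identity.
#'
#' @slot kaAvg geometric mean association rate, M^-1 s^-1.
#' @slot kdAvg geometric mean dissociation rate, s^-1.
#' @slot KDAvg geometric mean dissociation constant, M.
#' @slot n number of members averaged.
#' @exportClass FamilyKinetics
setClass("FamilyKinetics",
  representation(kaAvg = "numeric", kdAvg = "numeric", KDAvg = "numeric",
                 n = "integer")
)

setValidity("FamilyKinetics", function(object) {
  if (abs(log(object@KDAvg) - (log(object@kdAvg) - log(object@kaAvg))) > 1e-8)
    "KDAvg must equal kdAvg / kaAvg (geometric averaging identity)"
  else TRUE
})

#' Simulated or imported SPR sensorgram
#'
#' Response-versus-time traces for a concentration series with a shared
#' association/dissociation phase boundary.
#'
#' @slot concentrations analyte concentrations, M.
#' @slot times strictly increasing time grid, s.
#' @slot response matrix of response units, `length(times)` rows, one column
#'   per concentration.
#' @slot assocEnd end of the association phase, s.
#' @slot dissocEnd end of the dissociation phase, s.
#' @exportClass Sensorgram
setClass("Sensorgram",
  representation(
    concentrations = "numeric",
    times = "numeric",
    response = "matrix",
    assocEnd = "numeric",
    dissocEnd = "numeric"
  )
)

setValidity("Sensorgram", function(object) {
  msg <- character()
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!all(is.finite(object@response)))
    msg <- c(msg, "responses must be finite")
  if (nrow(object@response) != length(object@times) ||
      ncol(object@response) != length(object@concentrations))
    msg <- c(msg, "response must be times x concentrations")
  if (object@assocEnd >= object@dissocEnd)
    msg <- c(msg, "association phase must precede dissociation phase")
  if (any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be positive")
  if (length(msg)) msg else TRUE
})

#' Copy-number state of a selection library
#'
#' Molecule counts per explicitly tracked peptide species, plus aggregated
#' background bins standing in for the unenumerated low-affinity bulk of the
#' library (lognormal k_d quantile bins with representative kinetics).
#'
#' @slot species data.frame with columns `id`, `peptide` (random-region core),
#'   `dna`, `ka`, `kd`, `stickiness`, `family`, `count`.
#' @slot background data.frame with columns `id`, `ka`, `kd`, `stickiness`,
#'   `count`.
#' @exportClass LibraryState
setClass("LibraryState",
  representation(species = "data.frame", background = "data.frame")
)

.speciesCols <- c("id", "peptide", "dna", "ka", "kd", "stickiness", "family", "count")
.backgroundCols <- c("id", "ka", "kd", "stickiness", "count")

setValidity("LibraryState", function(object) {
  msg <- character()
  if (!all(.speciesCols %in% names(object@species)))
    msg <- c(msg, paste("species must have columns:", paste(.speciesCols, collapse = ", ")))
  if (!all(.backgroundCols %in% names(object@background)))
    msg <- c(msg, paste("background must have columns:", paste(.backgroundCols, collapse = ", ")))
  if (length(msg) == 0L) {
    if (nrow(object@species) && any(object@species$count < 0))
      msg <- c(msg, "species counts must be nonnegative")
    if (nrow(object@background) && any(object@background$count < 0))
      msg <- c(msg, "background counts must be nonnegative")
    if (nrow(object@species) && anyDuplicated(object@species$id))
      msg <- c(msg, "species ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of one selection campaign
#'
#' Physical and protocol parameters of a round of affinity selection. Defaults
#' reflect the modelled protocol: 30 min incubation with target near 100 nM,
#' one negative-selection pass, three bead washes, and PCR re-amplification
#' between rounds.
#'
#' @slot targetConc immobilised target concentration during incubation, M.
#' @slot incubationTime positive-selection incubation, s.
#' @slot nWashes number of bead washes after capture.
#' @slot tWash duration of a single wash, s.
#' @slot captureEfficiency end-to-end recovery probability of a bound molecule
#'   through capture, elution, reverse transcription and PCR rescue.
#' @slot nonspecificCarryover probability that a bead-stuck molecule is carried
#'   into the eluate, multiplied by per-species stickiness.
#' @slot negativeRounds number of negative-selection passes.
#' @slot pcrMutationRate per-base per-cycle point-mutation probability.
#' @slot pcrCycles PCR cycles per round.
#' @slot ribosomeBudget molecules translated per round (monosome budget).
#' @slot readDepth sequencing reads sampled per round.
#' @slot seed root RNG seed recorded with campaign outputs.
#' @exportClass SelectionConfig
setClass("SelectionConfig",
  representation(
    targetConc = "numeric",
    incubationTime = "numeric",
    nWashes = "integer",
    tWash = "numeric",
    captureEfficiency = "numeric",
    nonspecificCarryover = "numeric",
    negativeRounds = "integer",
    pcrMutationRate = "numeric",
    pcrCycles = "integer",
    ribosomeBudget = "numeric",
    readDepth = "numeric",
    seed = "integer"
  )
)

setValidity("SelectionConfig", function(object) {
  msg <- character()
  fr <- c(captureEfficiency = object@captureEfficiency,
          nonspecificCarryover = object@nonspecificCarryover,
          pcrMutationRate = object@pcrMutationRate)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    msg <- c(msg, paste(names(fr)[bad], "must lie in [0, 1]"))
  if (object@incubationTime <= 0) msg <- c(msg, "incubationTime must be positive")
  if (object@targetConc < 0) msg <- c(msg, "targetConc must be nonnegative")
  if (object@nWashes < 0 || object@tWash < 0)
    msg <- c(msg, "wash parameters must be nonnegative")
  if (object@negativeRounds < 0) msg <- c(msg, "negativeRounds must be nonnegative")
  if (object@ribosomeBudget <= 0) msg <- c(msg, "ribosomeBudget must be positive")
  if (object@readDepth < 1) msg <- c(msg, "readDepth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Outcome of one positive-selection round
#'
#' @slot roundIndex 1-based round number.
#' @slot inputTotal molecules entering positive selection.
#' @slot recoveredTotal molecules recovered from the target beads.
#' @slot recoveryRate `recoveredTotal / inputTotal`.
#' @slot postState [LibraryState] of the recovered pool.
#' @slot empty flag set when the round received an empty library.
#' @exportClass RoundResult
setClass("RoundResult",
  representation(
    roundIndex = "integer",
    inputTotal = "numeric",
    recoveredTotal = "numeric",
    recoveryRate = "numeric",
    postState = "LibraryState",
    empty = "logical"
  )
)

setValidity("RoundResult", function(object) {
  if (!object@empty &&
      (object@recoveryRate < 0 || object@recoveryRate > 1))
    "recoveryRate must lie in [0, 1]" else TRUE
})

#' Full multi-round campaign result
#'
#' @slot library library label.
#' @slot rounds list of [RoundResult].
#' @slot readTables list of [ReadCountTable], one per round.
#' @slot config the [SelectionConfig] used.
#' @slot seed root seed of the campaign.
#' @exportClass CampaignResult
setClass("CampaignResult",
  representation(
    library = "character",
    rounds = "list",
    readTables = "list",
    config = "SelectionConfig",
    seed = "integer"
  )
)

#' Per-round sequencing read counts
#'
#' @slot library library label.
#' @slot round round index.
#' @slot counts named numeric vector of read counts; names are random-region
#'   peptide sequences for tracked species and bin labels for aggregated
#'   background mass.
#' @slot isBackground logical, parallel to `counts`; background bins aggregate
#'   many distinct sequences each individually below the detection floor and
#'   are excluded from clone-level operations such as triage.
#' @slot metadata list of provenance details (e.g. discarded-read tallies).
#' @exportClass ReadCountTable
setClass("ReadCountTable",
  representation(
    library = "character",
    round = "integer",
    counts = "numeric",
    isBackground = "logical",
    metadata = "list"
  )
)

setValidity("ReadCountTable", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@isBackground))
    msg <- c(msg, "counts and isBackground must be parallel")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(object@counts) && is.null(names(object@counts)))
    msg <- c(msg, "counts must be named")
  if (length(msg)) msg else TRUE
})

#' Positive-clone triage configuration
#'
#' @slot abundanceThreshold minimum read fraction for a positive clone
#'   (default 0.02, i.e. reads exceeding 2% of the total).
#' @slot maxClones cap on the number of clones returned per library.
#' @exportClass TriageConfig
setClass("TriageConfig",
  representation(abundanceThreshold = "numeric", maxClones = "integer")
)

setValidity("TriageConfig", function(object) {
  msg <- character()
  if (object@abundanceThreshold <= 0 || object@abundanceThreshold >= 1)
    msg <- c(msg, "abundanceThreshold must lie in (0, 1)")
  if (object@maxClones < 1) msg <- c(msg, "maxClones must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Family clustering result
#'
#' @slot families named list; each element is a character vector of member
#'   ids (clusters of size >= 2), ordered by decreasing size.
#' @slot singletons character vector of ids in clusters of size 1.
#' @slot consensus named list parallel to `families`; each element is a list of
#'   per-position allowed-residue sets (character vectors; `"X"` marks a
#'   wildcard position).
#' @slot membership data.frame with columns `id`, `peptide`, `family`
#'   (`NA` for singletons).
#' @exportClass FamilyAssignment
setClass("FamilyAssignment",
  representation(
    families = "list",
    singletons = "character",
    consensus = "list",
    membership = "data.frame"
  )
)

setValidity("FamilyAssignment", function(object) {
  msg <- character()
  assigned <- c(unlist(object@families, use.names = FALSE), object@singletons)
  if (anyDuplicated(assigned))
    msg <- c(msg, "every peptide must belong to exactly one family or be a singleton")
  if (!setequal(names(object@families), names(object@consensus)))
    msg <- c(msg, "consensus must be keyed by family")
  if (any(vapply(object@consensus, function(cs)
        any(vapply(cs, length, integer(1)) == 0L), logical(1))))
    msg <- c(msg, "consensus positions must be nonempty sets")
  if (length(msg)) msg else TRUE
})

#' Lognormal dissociation-rate model parameters
#'
#' Parameters of the extreme-value model: across a random library, log10 of
#' the dissociation rate is taken to be normally distributed, and the best
#' binder of a library of size N is the minimum of N draws.
#'
#' @slot mu mean of log10 k_d (log10 s^-1).
#' @slot sigma standard deviation of log10 k_d.
#' @slot N library size (number of unique members).
#' @exportClass EVTParams
setClass("EVTParams",
  representation(mu = "numeric", sigma = "numeric", N = "numeric")
)

setValidity("EVTParams", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be nonnegative")
  if (object@N < 1) msg <- c(msg, "N must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic campaign fixture
#'
#' Defines a complete, seed-reproducible emulation of a multi-library
#' selection study: the subset lineage with its diversity ladder and
#' translation budgets, planted binder families with kinetics sampled around
#' log-scale family centres, a lognormal nonbinder background, and the
#' sequencing depth.
#'
#' @slot libraries data.frame with columns `name`, `diversity`, `parent`,
#'   `dilution`, `group`, `budgetRound1`.
#' @slot families data.frame with columns `family`, `phi` (fraction of
#'   sequence space occupied by the family, hence its initial frequency),
#'   `kaCenter`, `kdCenter`, `jitter` (log10 member jitter), `maxMembers`.
#' @slot backgroundMu mean log10 k_d of the nonbinder background.
#' @slot backgroundSigma sd of log10 k_d of the background.
#' @slot backgroundBins number of aggregated background quantile bins.
#' @slot backgroundKa representative background association rate, M^-1 s^-1.
#' @slot stickiness nonspecific bead-binding probability applied to all
#'   species and background bins.
#' @slot rounds number of selection rounds.
#' @slot readDepth sequencing reads per round.
#' @slot design the [LibraryDesign] used to emit DNA.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    libraries = "data.frame",
    families = "data.frame",
    backgroundMu = "numeric",
    backgroundSigma = "numeric",
    backgroundBins = "integer",
    backgroundKa = "numeric",
    stickiness = "numeric",
    rounds = "integer",
    readDepth = "numeric",
    design = "LibraryDesign"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (nrow(object@libraries) && any(object@libraries$diversity <= 0))
    msg <- c(msg, "library diversities must be positive")
  if (object@readDepth < 1) msg <- c(msg, "readDepth must be >= 1")
  if (nrow(object@families)) {
    if (any(object@families$phi <= 0 | object@families$phi >= 1))
      msg <- c(msg, "family phi must lie in (0, 1)")
    if (any(object@families$kaCenter <= 0 | object@families$kdCenter <= 0))
      msg <- c(msg, "family kinetic centres must be positive")
  }
  if (length(msg)) msg else TRUE
})
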