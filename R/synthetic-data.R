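## Seeded generator of complete campaign fixtures emulating the modelled
## study: a five-library, two-lineage diversity ladder with planted binder
## families around log-scale kinetic centres and a lognormal nonbinder
## background, aggregated into quantile bins.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

## NNK codons per amino acid (TAG excluded: generated constructs carry no
## in-frame stop in the random region).
nnkCodonsByAA <- function() {
  codons <- nnkCodons()
  aa <- Biostrings::GENETIC_CODE[codons]
  split(codons[aa != "*"], aa[aa != "*"])
}

#' Default synthetic-fixture specification
#'
#' Encodes the emulated study conditions: the five-library two-group lineage
#' with measured diversities 2.9e6 / 2.5e8 / 2.2e10 / 3.6e12 / 1.1e14 and
#' their round-1 translation budgets (1.8e12 molecules at 2.5 uL for the
#' smaller libraries, 3.6e12 at 5 uL for E12, 1.1e14 at 150 uL for E14);
#' four planted binder families whose kinetic centres are the log-scale
#' family averages of the modelled study (F-I 5.9e5 / 4.2e-3, F-II 1.1e5 /
#' 4.5e-3, F-III 5.7e5 / 45e-3, F-IV 2.4e5 / 52e-3) with 0.15 log10 member
#' jitter, plus one unique high-diversity-only binder; and a lognormal
#' nonbinder background (log10 kd ~ N(0, 0.5)) in 100 aggregated quantile
#' bins with a representative association rate well below the 2e4 /M/s
#' association threshold. Family sequence-space fractions `phi` set the
#' Poisson presence/absence pattern across the ladder (the fast-kd family in
#' every library, the rarer slow-kd families only at higher diversity).
#'
#' @param rounds selection rounds (default 7).
#' @param readDepth reads per round (default 1e5).
#' @param design a [LibraryDesign-class].
#' @return a [FixtureSpec-class] object.
#' @examples
#' defaultFixtureSpec()
#' @export
defaultFixtureSpec <- function(rounds = 7L, readDepth = 1e5,
                               design = LibraryDesign()) {
  libraries <- data.frame(
    name = c("E6", "E8", "E10", "E12", "E14"),
    diversity = c(2.9e6, 2.5e8, 2.2e10, 3.6e12, 1.1e14),
    parent = c("E10", "E12", "E14", NA, NA),
    dilution = c(1e4, 1e4, 1e4, 1, 1),
    group = c("1", "2", "1", "2", "1"),
    budgetRound1 = c(1.8e12, 1.8e12, 1.8e12, 3.6e12, 1.1e14),
    stringsAsFactors = FALSE)
  families <- data.frame(
    family = c("F-I", "F-II", "F-III", "F-IV", "U-1"),
    phi = c(4e-9, 4e-10, 1e-8, 3e-6, 1e-13),
    kaCenter = c(5.9e5, 1.1e5, 5.7e5, 2.4e5, 2e5),
    kdCenter = c(4.2e-3, 4.5e-3, 45e-3, 52e-3, 2e-3),
    jitter = c(0.15, 0.15, 0.15, 0.15, 0.15),
    maxMembers = c(6L, 6L, 4L, 2L, 1L),
    stringsAsFactors = FALSE)
  new("FixtureSpec", libraries = libraries, families = families,
      backgroundMu = 0, backgroundSigma = 0.5, backgroundBins = 100L,
      backgroundKa = 100, stickiness = 2e-3, rounds = as.integer(rounds),
      readDepth = readDepth, design = design)
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d libraries (diversity %.3g..%.3g), %d planted families, %d rounds\n",
    nrow(object@libraries), min(object@libraries$diversity),
    max(object@libraries$diversity), nrow(object@families), object@rounds))
})

## Poisson draw that stays usable for huge lambda.
.rpoisLarge <- function(lambda) {
  if (lambda < 1e9) stats::rpois(1L, lambda)
  else max(0, round(stats::rnorm(1L, lambda, sqrt(lambda))))
}

## Random peptide of length L over the 20 amino acids.
.randomPeptide <- function(L) paste(sample(AA20, L, replace = TRUE),
                                    collapse = "")

## Family consensus motifs: random 15-mers with pairwise Hamming distance
## >= minDist, found by rejection. Deterministic given the RNG state.
.generateMotifs <- function(nFam, L, minDist = 14L) {
  motifs <- character(0)
  while (length(motifs) < nFam) {
    cand <- .randomPeptide(L)
    if (!length(motifs) ||
        all(vapply(motifs, function(m)
          sum(strsplit(m, "")[[1L]] != strsplit(cand, "")[[1L]]) >= minDist,
          logical(1))))
      motifs <- c(motifs, cand)
  }
  motifs
}

## Variant of a motif with k mismatches at random positions.
.variantOf <- function(motif, k) {
  ch <- strsplit(motif, "")[[1L]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Encode a peptide as NNK codons, choosing one synonymous codon per residue.
.encodeNnk <- function(peptide, codonMap) {
  ch <- strsplit(peptide, "")[[1L]]
  paste(vapply(ch, function(a) {
    opts <- codonMap[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

## Full construct DNA for a random-region peptide.
.constructDna <- function(randomRegion, design, codonMap) {
  paste0("ATG", .encodeNnk(randomRegion, codonMap),
         if (design@fixedCys) "TGT" else "", design@linkerDna)
}

#' Generate one planted library state with ground truth
#'
#' Samples the planted families into the library: the number of distinct
#' family variants present is Poisson with mean `phi * diversity` (so rare
#' families are probabilistically lost from small libraries, the
#' sampling-loss mechanism of the diversity ladder), capped at `maxMembers`
#' explicitly tracked variants that carry the family's whole copy mass.
#' Member kinetics are the family centre jittered on the log10 scale; member
#' sequences are variants of a per-family consensus motif (1-3 mismatches)
#' drawn per library, with the two sampling lineages guaranteed to share no
#' variant. The remaining molecule budget is the lognormal background in
#' equal-mass quantile bins.
#'
#' All libraries of the fixture are generated internally from the fixture
#' seed (consensus motifs and the cross-group variant registry are shared),
#' and the requested one is returned; the same seed therefore yields the same
#' library regardless of which libraries are inspected.
#'
#' @param spec a [FixtureSpec-class].
#' @param library library name from `spec@libraries$name`.
#' @param seed fixture seed.
#' @return list with `state` ([LibraryState-class]), `truth` (data.frame:
#'   `id`, `peptide`, `family`, `ka`, `kd`, `sampledVariants`) and
#'   `consensus` (named motif vector).
#' @examples
#' lib <- generatePlantedLibrary(defaultFixtureSpec(), "E8", seed = 42)
#' lib$state
#' @export
generatePlantedLibrary <- function(spec, library, seed = 1L) {
  all <- .generateAllLibraries(spec, seed)
  if (!library %in% names(all$libraries))
    stop("unknown library: ", library)
  c(all$libraries[[library]], list(consensus = all$consensus))
}

.generateAllLibraries <- function(spec, seed) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  seeds <- childSeeds(seed, 1L + nrow(spec@libraries))
  L <- spec@design@randomCodonCount
  codonMap <- nnkCodonsByAA()

  set.seed(seeds[1L])
  motifs <- stats::setNames(.generateMotifs(nrow(spec@families), L),
                            spec@families$family)

  usedByGroup <- list()   # variant peptides assigned so far, per lineage group
  out <- vector("list", nrow(spec@libraries))
  names(out) <- spec@libraries$name
  for (i in seq_len(nrow(spec@libraries))) {
    lib <- spec@libraries[i, ]
    set.seed(seeds[1L + i])
    D <- lib$diversity
    B <- lib$budgetRound1
    copiesPerSeq <- B / D
    otherGroups <- setdiff(names(usedByGroup), lib$group)
    forbidden <- unlist(usedByGroup[otherGroups], use.names = FALSE)

    rows <- list()
    truth <- list()
    for (f in seq_len(nrow(spec@families))) {
      fam <- spec@families[f, ]
      nSampled <- .rpoisLarge(fam$phi * D)
      if (nSampled == 0) next
      nExplicit <- min(nSampled, fam$maxMembers)
      totalCopies <- round(nSampled * copiesPerSeq)
      if (totalCopies < 1) next
      shares <- rmultinomLarge(totalCopies, rep(1, nExplicit))
      for (m in seq_len(nExplicit)) {
        repeat {
          pep <- .variantOf(motifs[[fam$family]], sample(1:3, 1L))
          if (!pep %in% forbidden &&
              !any(vapply(rows, function(r) r$peptide == pep, logical(1))))
            break
        }
        usedByGroup[[lib$group]] <- c(usedByGroup[[lib$group]], pep)
        jit <- 10^stats::rnorm(2L, 0, fam$jitter)
        id <- sprintf("%s-%s-%d", lib$name, fam$family, m)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, peptide = pep,
          dna = .constructDna(pep, spec@design, codonMap),
          ka = fam$kaCenter * jit[1L], kd = fam$kdCenter * jit[2L],
          stickiness = spec@stickiness, family = fam$family,
          count = shares[m], stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, peptide = pep, family = fam$family,
          ka = fam$kaCenter * jit[1L], kd = fam$kdCenter * jit[2L],
          sampledVariants = nSampled, stringsAsFactors = FALSE)
      }
    }
    species <- if (length(rows)) do.call(rbind, rows) else emptySpeciesTable()
    plantedTotal <- sum(species$count)

    nb <- spec@backgroundBins
    z <- stats::qnorm(stats::ppoints(nb))
    bgTotal <- max(B - plantedTotal, 0)
    bgCounts <- floor(rep(bgTotal / nb, nb))
    bgCounts[1L] <- bgCounts[1L] + (bgTotal - sum(bgCounts))
    background <- data.frame(
      id = sprintf("bin%03d", seq_len(nb)),
      ka = rep(spec@backgroundKa, nb),
      kd = 10^(spec@backgroundMu + spec@backgroundSigma * z),
      stickiness = rep(spec@stickiness, nb),
      count = bgCounts, stringsAsFactors = FALSE)

    out[[lib$name]] <- list(
      state = LibraryState(species, background),
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(id = character(), peptide = character(),
                   family = character(), ka = numeric(), kd = numeric(),
                   sampledVariants = numeric(), stringsAsFactors = FALSE))
  }
  list(libraries = out, consensus = motifs)
}

#' Generate a complete multi-library campaign fixture
#'
#' Bundles every library of the spec with its selection configuration and
#' per-round translation budgets (the round-1 budget is library-specific; all
#' later rounds use the common 2.5 uL-scale budget), plus the ground-truth
#' family map. Optionally writes the bundle to a directory as plain-text
#' files: per-library FASTA of planted construct DNA, a ground-truth TSV, the
#' consensus motifs, and a YAML config.
#'
#' @param spec a [FixtureSpec-class].
#' @param seed fixture seed; all content is a deterministic function of
#'   `(spec, seed)`.
#' @param dir optional output directory.
#' @param config a [SelectionConfig-class] template; its seed is set to
#'   `seed`.
#' @return list with `spec`, `seed`, `config`, `consensus`, and `libraries`
#'   (per library: `state`, `truth`, `budgets`).
#' @export
generateCampaignFixture <- function(spec = defaultFixtureSpec(), seed = 1L,
                                    dir = NULL,
                                    config = SelectionConfig()) {
  all <- .generateAllLibraries(spec, seed)
  config@seed <- as.integer(seed)
  config@readDepth <- spec@readDepth
  libs <- lapply(names(all$libraries), function(nm) {
    lib <- all$libraries[[nm]]
    r1 <- spec@libraries$budgetRound1[spec@libraries$name == nm]
    lib$budgets <- c(r1, rep(config@ribosomeBudget, spec@rounds))
    lib
  })
  names(libs) <- names(all$libraries)
  bundle <- list(spec = spec, seed = as.integer(seed), config = config,
                 consensus = all$consensus, libraries = libs)
  if (!is.null(dir)) writeCampaignFixture(bundle, dir)
  bundle
}

#' Sample a sequencing read-count table from a library state
#'
#' Multinomial draw of `depth` reads proportional to molecule counts; tracked
#' species are keyed by their random-region peptide, background bins by their
#' bin label (flagged in `isBackground`). Identical peptides (e.g. a PCR
#' mutant that converged on an existing sequence) are aggregated.
#'
#' @param state a nonempty [LibraryState-class].
#' @param depth number of reads (>= 1).
#' @param seed RNG seed.
#' @param library,round labels recorded on the table.
#' @return a [ReadCountTable-class].
#' @export
sampleReadCounts <- function(state, depth, seed = 1L, library = "lib",
                             round = 1L) {
  stopifnot(is(state, "LibraryState"), depth >= 1)
  total <- totalMolecules(state)
  if (total <= 0) stop("cannot sample reads from an empty library state")
  set.seed(as.integer(seed))
  sp <- state@species
  keyS <- ifelse(is.na(sp$peptide), paste0("dead:", sp$id), sp$peptide)
  keys <- c(keyS, state@background$id)
  isBg <- c(rep(FALSE, nrow(sp)), rep(TRUE, nrow(state@background)))
  cnt <- c(sp$count, state@background$count)
  reads <- as.numeric(stats::rmultinom(1L, as.integer(depth), cnt))
  keep <- reads > 0
  agg <- tapply(reads[keep], keys[keep], sum)
  isBgAgg <- tapply(isBg[keep], keys[keep], any)
  ord <- order(names(agg))
  ReadCountTable(stats::setNames(as.numeric(agg)[ord], names(agg)[ord]),
                 library = library, round = round,
                 isBackground = as.logical(isBgAgg)[ord],
                 metadata = list(depth = depth, seed = seed))
}
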