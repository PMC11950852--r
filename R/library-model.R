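## Library architecture and scale arithmetic: NNK sequence space, ribosome and
## mRNA budgets, subset lineages.

AVOGADRO <- 6.02214076e23

#' The 32 NNK codons
#'
#' NNK degenerate codons have N = A/C/G/T at the first two positions and
#' K = G/T at the third; the 32 codons cover all 20 amino acids (plus the
#' amber stop TAG).
#'
#' @return character vector of 32 DNA codons.
#' @examples
#' length(nnkCodons())
#' @export
nnkCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
}

#' Construct a display-library design
#'
#' @param randomCodonCount number of NNK codons in the random region
#'   (default 15).
#' @param initiatorSymbol single-letter token used for the reprogrammed
#'   initiator (N-chloroacetyl-L-Tyr); lowercase `"y"` by default so it is
#'   distinguishable from genome-encoded Tyr.
#' @param fixedCys whether the fixed downstream Cys codon (UGU) is present.
#' @param linkerPeptide linker residue string.
#' @param linkerDna codons encoding the linker.
#' @return a [LibraryDesign-class] object.
#' @examples
#' LibraryDesign()
#' @export
LibraryDesign <- function(randomCodonCount = 15,
                          initiatorSymbol = "y",
                          fixedCys = TRUE,
                          linkerPeptide = "SGGLTN",
                          linkerDna = "TCCGGCGGATTAACTAAC") {
  new("LibraryDesign",
      randomCodonCount = randomCodonCount,
      initiatorSymbol = initiatorSymbol,
      fixedCys = fixedCys,
      linkerPeptide = linkerPeptide,
      linkerDna = normalizeDna(linkerDna),
      degenerateAlphabet = nnkCodons())
}

setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign: ", object@initiatorSymbol, "-(NNK)",
      object@randomCodonCount,
      if (object@fixedCys) "-C" else "", "-", object@linkerPeptide, "\n",
      "  DNA diversity of random region: ",
      format(nnkTheoreticalDiversity(object@randomCodonCount), digits = 3),
      "\n", sep = "")
})

#' Construct a library subset
#'
#' Subsets carry their estimated diversity verbatim: measured daughter
#' diversities need not equal the parent's divided by the dilution factor, so
#' stated values are never recomputed.
#'
#' @param name subset label.
#' @param estimatedDiversity unique-sequence count.
#' @param parent parent label or `NA`.
#' @param dilutionFactor dilution relative to the parent (1 for mothers).
#' @param group lineage group label.
#' @return a [LibrarySubset-class] object.
#' @export
LibrarySubset <- function(name, estimatedDiversity, parent = NA_character_,
                          dilutionFactor = 1, group = "1") {
  new("LibrarySubset", name = name, estimatedDiversity = estimatedDiversity,
      parent = parent, dilutionFactor = dilutionFactor,
      group = as.character(group))
}

setMethod("show", "LibrarySubset", function(object) {
  cat("LibrarySubset ", object@name, ": diversity ",
      format(object@estimatedDiversity, digits = 3),
      if (!is.na(object@parent))
        paste0(" (from ", object@parent, ", 1/",
               format(object@dilutionFactor, digits = 3), ")") else "",
      " [group ", object@group, "]\n", sep = "")
})

#' The five-library study lineage
#'
#' Returns the two-lineage library ladder of the modelled study: group 1
#' (E14 -> E10 -> E6) and group 2 (E12 -> E8), with daughter subsets diluted
#' by four orders of magnitude and the measured diversities stored verbatim
#' (1.1e14, 3.6e12, 2.2e10, 2.5e8, 2.9e6).
#'
#' @return named list of [LibrarySubset-class] objects.
#' @examples
#' librarySubsets()[["E6"]]
#' @export
librarySubsets <- function() {
  list(
    E14 = LibrarySubset("E14", 1.1e14, group = "1"),
    E10 = LibrarySubset("E10", 2.2e10, parent = "E14", dilutionFactor = 1e4, group = "1"),
    E6  = LibrarySubset("E6",  2.9e6,  parent = "E10", dilutionFactor = 1e4, group = "1"),
    E12 = LibrarySubset("E12", 3.6e12, group = "2"),
    E8  = LibrarySubset("E8",  2.5e8,  parent = "E12", dilutionFactor = 1e4, group = "2")
  )
}

#' Construct a translation budget
#'
#' @param volume reaction volume, µL.
#' @param ribosomeConc ribosome concentration, pmol/µL (default 1.2).
#' @return a [TranslationBudget-class] object.
#' @export
TranslationBudget <- function(volume, ribosomeConc = 1.2) {
  new("TranslationBudget", volume = volume, ribosomeConc = ribosomeConc)
}

#' Theoretical diversity of an NNK random region
#'
#' DNA-level sequence diversity of L NNK codons: \eqn{32^L}. For L = 15 this
#' is about 3.8e22. Values above 2^53 are necessarily approximate doubles.
#'
#' @param L number of NNK codons (nonnegative integer).
#' @return `32^L`.
#' @examples
#' nnkTheoreticalDiversity(15) # ~3.8e22
#' nnkTheoreticalDiversity(2)  # 1024
#' @export
nnkTheoreticalDiversity <- function(L) {
  if (length(L) != 1L || !is.finite(L) || L < 0 || L != floor(L))
    stop("L must be a single nonnegative integer")
  32^L
}

#' Number of ribosome molecules in a translation budget
#'
#' `volume * ribosomeConc * 1e-12 * N_A`. At the default 1.2 pmol/µL this is
#' 7.2e11 ribosomes per µL; under the monosome assumption it equals the
#' peptide-mRNA fusion budget.
#'
#' @param budget a [TranslationBudget-class].
#' @return molecule count.
#' @examples
#' ribosomeMolecules(TranslationBudget(5)) # 3.6e12
#' @export
ribosomeMolecules <- function(budget) {
  stopifnot(is(budget, "TranslationBudget"))
  budget@volume * budget@ribosomeConc * 1e-12 * AVOGADRO
}

#' mRNA amount saturating every ribosome once
#'
#' Under the monosome assumption the mRNA added must equal the ribosomes
#' present, i.e. `volume * ribosomeConc` pmol.
#'
#' @param budget a [TranslationBudget-class].
#' @return mRNA amount in pmol.
#' @examples
#' requiredMrnaPmol(TranslationBudget(150)) # 180 pmol
#' @export
requiredMrnaPmol <- function(budget) {
  stopifnot(is(budget, "TranslationBudget"))
  budget@volume * budget@ribosomeConc
}

#' Fold suppression of sequence diversity by a selection round
#'
#' The reciprocal of the recovery rate: a round recovering 0.0005% of input
#' molecules suppresses diversity by about 2e5-fold.
#'
#' @param recoveryRate recovered fraction, in (0, 1].
#' @return suppression fold.
#' @examples
#' diversitySuppression(5e-6) # 2e5
#' @export
diversitySuppression <- function(recoveryRate) {
  if (any(!is.finite(recoveryRate)) || any(recoveryRate <= 0) ||
      any(recoveryRate > 1))
    stop("recoveryRate must lie in (0, 1]")
  1 / recoveryRate
}

#' Derive a daughter library subset by dilution
#'
#' A dilution by factor f of a library holding one copy per sequence thins
#' each sequence independently with probability 1/f, so the expected retained
#' diversity is the parent's divided by f. Lineage is recorded on the child.
#'
#' @param parent a [LibrarySubset-class].
#' @param dilutionFactor dilution factor, >= 1.
#' @param name child label (default derived from the parent).
#' @return a [LibrarySubset-class] for the daughter.
#' @examples
#' e14 <- LibrarySubset("E14", 1.1e14)
#' deriveSubset(e14, 1e4, "E10calc")
#' @export
deriveSubset <- function(parent, dilutionFactor, name = NULL) {
  stopifnot(is(parent, "LibrarySubset"))
  if (!is.finite(dilutionFactor) || dilutionFactor < 1)
    stop("dilutionFactor must be >= 1")
  childDiv <- parent@estimatedDiversity / dilutionFactor
  nm <- name %||% paste0(parent@name, "/", format(dilutionFactor, digits = 3))
  if (dilutionFactor == 1)
    return(LibrarySubset(nm, parent@estimatedDiversity, parent = parent@name,
                         dilutionFactor = 1 + 1e-12, group = parent@group))
  LibrarySubset(nm, childDiv, parent = parent@name,
                dilutionFactor = dilutionFactor, group = parent@group)
}

#' Expected unique sequences when sampling from a large pool
#'
#' Poissonization formula for the expected number of distinct sequences seen
#' when drawing n molecules from a pool of D equifrequent sequences:
#' \eqn{D (1 - e^{-n/D})}.
#'
#' @param n molecules sampled.
#' @param D pool diversity.
#' @return expected unique count.
#' @examples
#' expectedUniqueCount(1e6, 1e4) # ~1e4: pool saturated
#' @export
expectedUniqueCount <- function(n, D) {
  stopifnot(n >= 0, D > 0)
  D * (-expm1(-n / D))
}

## --- construct translation ---------------------------------------------

normalizeDna <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  gsub("U", "T", x, fixed = TRUE)
}

isNnkCodon <- function(codons) grepl("^[ACGT][ACGT][GT]$", codons)

splitCodons <- function(dna) {
  substring(dna, seq(1, nchar(dna) - 2, by = 3), seq(3, nchar(dna), by = 3))
}

#' Translate a display-construct nucleotide sequence
#'
#' Standard-table translation of the construct open reading frame, with the
#' initiator AUG rendered as the design's acylated-Tyr token. Random-region
#' codons are checked for NNK membership; an in-frame stop codon terminates
#' translation with a flag (the amber codon TAG is a legal NNK member and is
#' treated as a stop-flagged position; the reprogrammed read-through of the
#' designed downstream UAG is not modelled).
#'
#' @param dna nucleotide sequence (DNA or RNA alphabet; whitespace ignored).
#' @param design a [LibraryDesign-class].
#' @return list with elements `peptide` (full translation, initiator token
#'   first), `core` (initiator + random region + fixed Cys),
#'   `randomRegion` (residues of the random region), `nnkValid` (logical per
#'   random-region codon), `stopFlag`, `stopPosition` (codon index or `NA`),
#'   `cysOk` (fixed Cys present where the design requires it) and `valid`
#'   (no stop in the random region and architecture intact).
#' @examples
#' d <- LibraryDesign()
#' translateDisplayConstruct("AUG UGU UCC GGC GGA UUA ACU AAC", d)$peptide
#' @export
translateDisplayConstruct <- function(dna, design = LibraryDesign()) {
  stopifnot(is(design, "LibraryDesign"))
  dna <- normalizeDna(dna)
  if (nchar(dna) == 0L || nchar(dna) %% 3L != 0L)
    stop("sequence length must be a positive multiple of 3")
  if (substr(dna, 1L, 3L) != "ATG")
    stop("construct must start with the initiator AUG")
  codons <- splitCodons(dna)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa[1L] <- design@initiatorSymbol

  L <- design@randomCodonCount
  rrIdx <- if (L > 0 && length(codons) >= 2L)
    seq(2L, min(1L + L, length(codons))) else integer()
  nnkValid <- isNnkCodon(codons[rrIdx])

  stopPos <- which(aa == "*")
  stopFlag <- length(stopPos) > 0L
  stopPosition <- if (stopFlag) stopPos[1L] else NA_integer_
  pepEnd <- if (stopFlag) stopPosition - 1L else length(aa)
  peptide <- paste(aa[seq_len(pepEnd)], collapse = "")

  cysIdx <- 2L + L
  cysOk <- !design@fixedCys ||
    (length(aa) >= cysIdx && !is.na(aa[cysIdx]) && aa[cysIdx] == "C" &&
     cysIdx <= pepEnd)
  coreEnd <- min(cysIdx, pepEnd)
  core <- paste(aa[seq_len(max(coreEnd, 0L))], collapse = "")
  randomRegion <- paste(aa[rrIdx[rrIdx <= pepEnd]], collapse = "")
  stopInRandom <- stopFlag && stopPosition %in% rrIdx

  list(peptide = peptide,
       core = core,
       randomRegion = randomRegion,
       nnkValid = nnkValid,
       stopFlag = stopFlag,
       stopPosition = stopPosition,
       cysOk = cysOk,
       valid = !stopInRandom && cysOk && length(rrIdx) == L &&
         all(nnkValid))
}

#' Vectorised construct translation for read streams
#'
#' Applies the same architecture checks as [translateDisplayConstruct()] to a
#' set of reads at once. Reads that are not a multiple of 3, do not start with
#' AUG, contain a stop or non-NNK codon in the random region, or lack the
#' fixed Cys are marked invalid with a reason.
#'
#' @param dna character vector or `Biostrings::DNAStringSet` of reads.
#' @param design a [LibraryDesign-class].
#' @return data.frame with columns `dna`, `randomRegion`, `core`, `valid`,
#'   `reason` (`"ok"` when valid).
#' @export
translateConstructSet <- function(dna, design = LibraryDesign()) {
  dna <- normalizeDna(as.character(dna))
  n <- length(dna)
  out <- data.frame(dna = dna,
                    randomRegion = NA_character_,
                    core = NA_character_,
                    valid = FALSE,
                    reason = "ok",
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  len <- nchar(dna)
  L <- design@randomCodonCount
  minLen <- 3L * (2L + L)
  bad <- len %% 3L != 0L | len < minLen
  out$reason[bad] <- "frame"
  noStart <- !bad & substr(dna, 1L, 3L) != "ATG"
  out$reason[noStart] <- "no_start"

  ok <- which(out$reason == "ok")
  if (length(ok)) {
    rr <- substr(dna[ok], 4L, 3L + 3L * L)
    cysCodon <- substr(dna[ok], 4L + 3L * L, 6L + 3L * L)
    code <- Biostrings::GENETIC_CODE
    rrCodons <- matrix(unlist(lapply(rr, splitCodons)), nrow = length(ok),
                       byrow = TRUE)
    nnkOk <- rowSums(!matrix(isNnkCodon(rrCodons), nrow = length(ok))) == 0L
    aaMat <- matrix(code[rrCodons], nrow = length(ok))
    hasStop <- rowSums(aaMat == "*", na.rm = TRUE) > 0L |
      rowSums(is.na(aaMat)) > 0L
    cysOk <- !design@fixedCys | code[cysCodon] %in% "C"
    out$reason[ok[!nnkOk]] <- "non_nnk"
    out$reason[ok[nnkOk & hasStop]] <- "stop_in_random"
    out$reason[ok[nnkOk & !hasStop & !cysOk]] <- "missing_cys"
    good <- ok[nnkOk & !hasStop & cysOk]
    if (length(good)) {
      idx <- match(good, ok)
      rrPep <- apply(aaMat[idx, , drop = FALSE], 1L, paste, collapse = "")
      out$randomRegion[good] <- rrPep
      out$core[good] <- paste0(design@initiatorSymbol, rrPep,
                               if (design@fixedCys) "C" else "")
      out$valid[good] <- TRUE
    }
  }
  out
}
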