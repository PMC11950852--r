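## NGS-side analysis: reads to counts, abundance triage, cross-library
## deduplication, consensus-family clustering, population trajectories and
## kinetic scatter tables.

#' Construct a read-count table
#'
#' @param counts named numeric read counts (names are random-region peptides,
#'   or bin labels for aggregated background mass).
#' @param library library label.
#' @param round round index.
#' @param isBackground logical parallel to `counts` (default all `FALSE`).
#' @param metadata provenance list.
#' @return a [ReadCountTable-class] object.
#' @export
ReadCountTable <- function(counts, library = "lib", round = 1L,
                           isBackground = rep(FALSE, length(counts)),
                           metadata = list()) {
  new("ReadCountTable", library = library, round = as.integer(round),
      counts = counts, isBackground = isBackground, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("readCounts", "ReadCountTable", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("totalReads", "ReadCountTable", function(object) sum(object@counts))

setMethod("show", "ReadCountTable", function(object) {
  cat(sprintf(
    "ReadCountTable [%s, round %d]: %d entries, %.4g reads (%d background bins)\n",
    object@library, object@round, length(object@counts), sum(object@counts),
    sum(object@isBackground)))
})

#' Construct a triage configuration
#'
#' @param abundanceThreshold positive-clone read-fraction threshold
#'   (default 0.02).
#' @param maxClones cap on clones returned (default 7, the "top 6 or 7" rule's
#'   upper value; the choice between 6 and 7 is not algorithmic, so the cap is
#'   configurable).
#' @return a [TriageConfig-class] object.
#' @export
TriageConfig <- function(abundanceThreshold = 0.02, maxClones = 7L) {
  new("TriageConfig", abundanceThreshold = abundanceThreshold,
      maxClones = as.integer(maxClones))
}

#' Count construct reads from a FASTA/FASTQ stream
#'
#' Reads are translated with the construct architecture checks of
#' [translateConstructSet()]; frame-invalid, start-less, stop-containing and
#' non-NNK reads are discarded with per-reason tallies, and identical
#' random-region peptides are aggregated.
#'
#' @param reads path to a FASTA or FASTQ file, or a
#'   `Biostrings::DNAStringSet` / character vector of reads.
#' @param design a [LibraryDesign-class].
#' @param library,round labels recorded on the table.
#' @param format `"fasta"` or `"fastq"`; guessed from the file extension when
#'   `reads` is a path.
#' @return a [ReadCountTable-class]; discard tallies are in
#'   `@metadata$excluded`, and a zero-valid-read input yields an empty table
#'   flagged in `@metadata$empty`.
#' @export
countsFromReads <- function(reads, design = LibraryDesign(), library = "lib",
                            round = 1L, format = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- format %||%
      (if (grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE))
         "fastq" else "fasta")
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  tr <- translateConstructSet(reads, design)
  excluded <- table(tr$reason[!tr$valid])
  valid <- tr$randomRegion[tr$valid]
  counts <- if (length(valid)) {
    tab <- table(valid)
    stats::setNames(as.numeric(tab), names(tab))
  } else numeric()
  ReadCountTable(counts, library = library, round = round,
                 metadata = list(
                   excluded = stats::setNames(as.numeric(excluded),
                                              names(excluded)),
                   nInput = nrow(tr),
                   empty = length(valid) == 0L))
}

#' Triage positive clones by read abundance
#'
#' Sequences whose read fraction strictly exceeds the abundance threshold are
#' ranked by count (descending, lexicographic tie-break) and truncated at the
#' clone cap. Aggregated background bins are excluded: each bin pools many
#' distinct sequences that are individually below the detection floor.
#'
#' @param table a [ReadCountTable-class].
#' @param cfg a [TriageConfig-class].
#' @return data.frame with columns `sequence`, `count`, `fraction`, `rank`
#'   (zero rows for an empty table).
#' @examples
#' tab <- ReadCountTable(c(AAA = 5000, BBB = 1900, CCC = 100) ,
#'                       metadata = list())
#' triagePositiveClones(tab, TriageConfig())
#' @export
triagePositiveClones <- function(table, cfg = TriageConfig()) {
  stopifnot(is(table, "ReadCountTable"), is(cfg, "TriageConfig"))
  empty <- data.frame(sequence = character(), count = numeric(),
                      fraction = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (!length(table@counts)) return(empty)
  total <- sum(table@counts)
  if (total <= 0) return(empty)
  cnt <- table@counts[!table@isBackground]
  frac <- cnt / total
  keep <- which(frac > cfg@abundanceThreshold)
  if (!length(keep)) return(empty)
  ord <- keep[order(-cnt[keep], names(cnt)[keep])]
  ord <- ord[seq_len(min(length(ord), cfg@maxClones))]
  data.frame(sequence = names(cnt)[ord], count = as.numeric(cnt[ord]),
             fraction = as.numeric(frac[ord]), rank = seq_along(ord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Abundance detection floor of a sequencing run
#'
#' The library fraction resolvable by a single read, `1 / totalReads`: at the
#' typical 1e5 reads per round a read count of zero means an abundance below
#' 0.001%.
#'
#' @param table a [ReadCountTable-class] (or a total read count).
#' @return detection floor as a fraction.
#' @examples
#' detectionFloor(1e5) # 1e-5, i.e. 0.001%
#' @export
detectionFloor <- function(table) {
  total <- if (is(table, "ReadCountTable")) sum(table@counts) else table
  if (total <= 0) stop("total reads must be positive")
  1 / total
}

#' Deduplicate triaged clones across libraries
#'
#' Groups clones by exact peptide sequence across libraries and reports the
#' unique sequence set plus all cross-library identity pairs.
#'
#' @param selections named list: library label -> character vector of clone
#'   sequences (optionally named by clone ids).
#' @return list with `uniqueSequences`, `nUnique`, `nInput`, and
#'   `duplicatePairs` (data.frame: `sequence`, `clone1`, `clone2`).
#' @export
deduplicateAcrossLibraries <- function(selections) {
  stopifnot(is.list(selections))
  df <- do.call(rbind, lapply(names(selections) %||% seq_along(selections),
    function(lib) {
      x <- selections[[lib]]
      if (!length(x)) return(NULL)
      ids <- names(x) %||% paste0(lib, "-", seq_along(x))
      if (is.null(names(x))) names(x) <- ids
      data.frame(library = lib, clone = names(x), sequence = unname(x),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(df))
    return(list(uniqueSequences = character(), nUnique = 0L, nInput = 0L,
                duplicatePairs = data.frame(sequence = character(),
                                            clone1 = character(),
                                            clone2 = character())))
  uniq <- sort(unique(df$sequence))
  pairs <- do.call(rbind, lapply(split(df, df$sequence), function(g) {
    if (nrow(g) < 2L) return(NULL)
    cmb <- utils::combn(sort(g$clone), 2L)
    data.frame(sequence = g$sequence[1L], clone1 = cmb[1L, ],
               clone2 = cmb[2L, ], stringsAsFactors = FALSE)
  }))
  list(uniqueSequences = uniq, nUnique = length(uniq), nInput = nrow(df),
       duplicatePairs = pairs %||% data.frame(sequence = character(),
                                              clone1 = character(),
                                              clone2 = character()))
}

## Per-position consensus residue sets covering >= `cover` of the members.
## Greedy by frequency; positions needing more than `maxSet` residues are
## wildcards ("X").
consensusSets <- function(peptides, cover = 2 / 3, maxSet = 2L) {
  m <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  lapply(seq_len(ncol(m)), function(j) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    freq <- as.numeric(tab) / nrow(m)
    k <- which(cumsum(freq) >= cover)[1L]
    if (is.na(k) || k > maxSet) "X" else sort(names(tab)[seq_len(k)])
  })
}

#' Render a consensus set list as a motif string
#'
#' @param sets list of per-position residue sets (from a
#'   [FamilyAssignment-class]).
#' @return motif string; multi-residue positions are bracketed, wildcards are
#'   `X`.
#' @export
renderConsensus <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = "/"), "]")
  }, character(1)), collapse = "")
}

#' Cluster equal-length peptides into consensus families
#'
#' Single-linkage clustering on Hamming distance: two peptides are linked when
#' they differ at no more than `maxMismatchFraction` of their positions, and
#' families are the connected components of the link graph (computed by
#' union-find, so the result is invariant to input order). Clusters of size
#' one are reported as singletons. Per-family consensus motifs are the
#' per-position residue sets covering at least two thirds of the members.
#'
#' The library core is fixed-length, so no gapped alignment is attempted;
#' unequal input lengths are an error.
#'
#' @param peptides character vector of equal-length residue strings,
#'   optionally named by clone ids (sequences themselves are used as ids
#'   otherwise).
#' @param maxMismatchFraction linkage threshold as a fraction of the length
#'   (default 0.5).
#' @return a [FamilyAssignment-class]; families are labelled `F-I`, `F-II`,
#'   ... by decreasing size (ties broken by first member id).
#' @examples
#' cl <- clusterFamilies(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC",
#'                         c = "WWWWWWWWWW"))
#' families(cl); singletons(cl)
#' @export
clusterFamilies <- function(peptides, maxMismatchFraction = 0.5) {
  if (!length(peptides)) stop("no peptides supplied")
  if (length(unique(nchar(peptides))) != 1L)
    stop("peptides must have equal length (gapped alignment is out of scope)")
  ids <- names(peptides) %||% unname(peptides)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(peptides)
  L <- nchar(peptides[1L])
  thr <- maxMismatchFraction * L

  ## order-invariant components: sort by id first, then union-find
  ord <- order(ids)
  pep <- unname(peptides)[ord]
  idsSorted <- ids[ord]
  d <- hammingMatrix(pep)
  linked <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  comp <- unionFindComponents(n, linked)

  groups <- split(seq_len(n), comp)
  sizes <- vapply(groups, length, integer(1))
  famGroups <- groups[sizes >= 2L]
  singleIdx <- unlist(groups[sizes == 1L], use.names = FALSE)

  ## label by decreasing size, ties by first (sorted) member id
  if (length(famGroups)) {
    firstId <- vapply(famGroups, function(g) idsSorted[g[1L]], character(1))
    ordFam <- order(-vapply(famGroups, length, integer(1)), firstId)
    famGroups <- famGroups[ordFam]
    labels <- paste0("F-", utils::as.roman(seq_along(famGroups)))
    famList <- stats::setNames(lapply(famGroups, function(g) idsSorted[g]),
                               labels)
    consensus <- stats::setNames(lapply(famGroups, function(g)
      consensusSets(pep[g])), labels)
  } else {
    famList <- stats::setNames(list(), character())
    consensus <- stats::setNames(list(), character())
  }
  memberFam <- rep(NA_character_, n)
  for (f in names(famList)) memberFam[match(famList[[f]], idsSorted)] <- f
  membership <- data.frame(id = idsSorted, peptide = pep, family = memberFam,
                           stringsAsFactors = FALSE)
  membership <- membership[order(match(membership$id, ids)), , drop = FALSE]
  rownames(membership) <- NULL
  new("FamilyAssignment", families = famList,
      singletons = sort(idsSorted[singleIdx]),
      consensus = consensus, membership = membership)
}

#' @rdname accessors
#' @export
setMethod("families", "FamilyAssignment", function(object) object@families)
#' @rdname accessors
#' @export
setMethod("singletons", "FamilyAssignment", function(object) object@singletons)
#' @rdname accessors
#' @export
setMethod("consensusMotifs", "FamilyAssignment", function(object)
  vapply(object@consensus, renderConsensus, character(1)))
#' @rdname accessors
#' @export
setMethod("membership", "FamilyAssignment", function(object) object@membership)

setMethod("show", "FamilyAssignment", function(object) {
  cat(sprintf("FamilyAssignment: %d families, %d singletons\n",
              length(object@families), length(object@singletons)))
  for (f in names(object@families))
    cat(sprintf("  %s (%d members): %s\n", f, length(object@families[[f]]),
                renderConsensus(object@consensus[[f]])))
})

#' Per-round population trajectories of species and families
#'
#' Converts a list of per-round read-count tables into per-round read
#' fractions for every sequence ever observed (absent-in-round sequences get
#' fraction zero, matching the treatment of a zero read count as negligible
#' abundance), plus family-level trajectories when an assignment is given.
#'
#' @param tables list of [ReadCountTable-class] for consecutive rounds of one
#'   library.
#' @param assignment optional [FamilyAssignment-class] whose membership maps
#'   sequences to families.
#' @return list with `species` (matrix: sequences x rounds, read fractions),
#'   `families` (matrix: families/singleton-or-unassigned/background x
#'   rounds; `NULL` without an assignment) and `rounds`.
#' @export
populationTrajectories <- function(tables, assignment = NULL) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "ReadCountTable")))
  libs <- unique(vapply(tables, slot, character(1), "library"))
  if (length(libs) != 1L)
    stop("tables must come from a single library (got: ",
         paste(libs, collapse = ", "), ")")
  rounds <- vapply(tables, slot, integer(1), "round")
  seqNames <- sort(unique(unlist(lapply(tables, function(t)
    names(t@counts)[!t@isBackground]))))
  species <- matrix(0, nrow = length(seqNames), ncol = length(tables),
                    dimnames = list(seqNames, paste0("round", rounds)))
  bgFrac <- numeric(length(tables))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    total <- sum(t@counts)
    if (total <= 0) next
    fg <- t@counts[!t@isBackground]
    species[match(names(fg), seqNames), j] <- fg / total
    bgFrac[j] <- sum(t@counts[t@isBackground]) / total
  }
  fam <- NULL
  if (!is.null(assignment)) {
    stopifnot(is(assignment, "FamilyAssignment"))
    mem <- assignment@membership
    famOf <- stats::setNames(mem$family, mem$peptide)
    grp <- famOf[seqNames]
    grp[is.na(grp)] <- "unassigned"
    famNames <- c(names(assignment@families), "unassigned", "background")
    fam <- matrix(0, nrow = length(famNames), ncol = length(tables),
                  dimnames = list(famNames, colnames(species)))
    for (f in setdiff(famNames, "background"))
      if (any(grp == f))
        fam[f, ] <- colSums(species[grp == f, , drop = FALSE])
    fam["background", ] <- bgFrac
  }
  list(species = species, families = fam, rounds = rounds)
}

#' Kinetic scatter table with best-binder flags
#'
#' Emits the plotting table behind a k_d-versus-k_a scatter of hit peptides:
#' one row per species with its rates, derived K_D, family and library, and a
#' flag on the species with the smallest K_D in each library (ties broken by
#' the lower k_d). Species with missing kinetics are listed with
#' `kineticsMissing = TRUE` and excluded from best-binder ranking.
#'
#' @param species data.frame with columns `id`, `ka`, `kd` and optionally
#'   `library`, `family`.
#' @return data.frame with added `KD`, `kineticsMissing` and `bestInLibrary`
#'   columns.
#' @export
kineticScatterTable <- function(species) {
  stopifnot(is.data.frame(species), all(c("id", "ka", "kd") %in% names(species)))
  out <- species
  if (is.null(out$library)) out$library <- "all"
  if (is.null(out$family)) out$family <- NA_character_
  out$KD <- out$kd / out$ka
  out$kineticsMissing <- !is.finite(out$ka) | !is.finite(out$kd)
  out$KD[out$kineticsMissing] <- NA_real_
  out$bestInLibrary <- FALSE
  for (lib in unique(out$library)) {
    i <- which(out$library == lib & !out$kineticsMissing)
    if (!length(i)) next
    best <- i[order(out$KD[i], out$kd[i], out$id[i])][1L]
    out$bestInLibrary[best] <- TRUE
  }
  out
}
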