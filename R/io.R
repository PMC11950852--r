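## Delimited-text readers and writers tying the pipeline stages together.
## Everything is plain text with explicit headers; every file written by a
## campaign run embeds the seed and a config hash for reproducibility.

#' Write a read-count table as TSV
#'
#' Columns: `library`, `round`, `sequence`, `count`, `fraction`,
#' `background`. Comment header lines carry provenance (seed, config hash)
#' when supplied.
#'
#' @param table a [ReadCountTable-class].
#' @param path output path.
#' @param provenance optional named character vector written as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
writeReadCountTable <- function(table, path, provenance = NULL) {
  stopifnot(is(table, "ReadCountTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  total <- sum(table@counts)
  df <- data.frame(library = table@library, round = table@round,
                   sequence = names(table@counts),
                   count = as.numeric(table@counts),
                   fraction = if (total > 0) as.numeric(table@counts) / total
                              else 0,
                   background = table@isBackground,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeReadCountTable()]
#'
#' @param path input path.
#' @return a [ReadCountTable-class].
#' @export
readReadCountTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c(sequence = "character"))
  ReadCountTable(stats::setNames(df$count, df$sequence),
                 library = as.character(df$library[1L] %||% "lib"),
                 round = df$round[1L] %||% 1L,
                 isBackground = df$background)
}

#' Write construct DNA sequences as FASTA
#'
#' @param dna named character vector (or the `species` table of a
#'   [LibraryState-class]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConstructFasta <- function(dna, path) {
  if (is.data.frame(dna)) dna <- stats::setNames(dna$dna, dna$id)
  x <- Biostrings::DNAStringSet(dna[!is.na(dna)])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read construct DNA sequences from FASTA
#'
#' @param path input path.
#' @return named character vector of DNA sequences.
#' @export
readConstructFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a subset lineage description
#'
#' Serialises a list of [LibrarySubset-class] objects to YAML (name, parent,
#' dilution, diversity, group).
#'
#' @param subsets list of [LibrarySubset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLineageConfig <- function(subsets, path) {
  yaml::write_yaml(lapply(subsets, function(s) list(
    name = s@name, diversity = s@estimatedDiversity,
    parent = if (is.na(s@parent)) NULL else s@parent,
    dilution = s@dilutionFactor, group = s@group)), path)
  invisible(path)
}

#' Read a subset lineage description
#'
#' @param path YAML path written by [writeLineageConfig()].
#' @return named list of [LibrarySubset-class].
#' @export
readLineageConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  subs <- lapply(raw, function(r)
    LibrarySubset(r$name, r$diversity, parent = r$parent %||% NA_character_,
                  dilutionFactor = r$dilution %||% 1,
                  group = as.character(r$group %||% "1")))
  stats::setNames(subs, vapply(subs, slot, character(1), "name"))
}

#' Serialise a selection config to YAML
#'
#' @param config a [SelectionConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionConfig <- function(config, path) {
  sl <- methods::slotNames("SelectionConfig")
  yaml::write_yaml(stats::setNames(lapply(sl, function(s) slot(config, s)), sl),
                   path)
  invisible(path)
}

#' Read a selection config from YAML
#'
#' Unknown keys are ignored; missing keys keep package defaults.
#'
#' @param path YAML path.
#' @return a [SelectionConfig-class].
#' @export
readSelectionConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), methods::formalArgs(SelectionConfig))
  do.call(SelectionConfig, raw[keep])
}

## md5 of a config file (or any file); used to stamp outputs.
configHash <- function(path) unname(tools::md5sum(path))

#' Write a campaign fixture bundle to a directory
#'
#' Emits, per library: a FASTA of planted construct DNA and a ground-truth
#' TSV; plus the consensus motifs, the lineage and the selection config.
#'
#' @param bundle result of [generateCampaignFixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCampaignFixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$libraries)) {
    lib <- bundle$libraries[[nm]]
    sp <- speciesTable(lib$state)
    if (nrow(sp))
      writeConstructFasta(sp, file.path(dir, paste0(nm, "_planted.fasta")))
    utils::write.table(lib$truth, file.path(dir, paste0(nm, "_truth.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(family = names(bundle$consensus),
               motif = unname(bundle$consensus)),
    file.path(dir, "consensus_motifs.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  lin <- bundle$spec@libraries
  yaml::write_yaml(list(seed = bundle$seed,
                        libraries = split(lin, seq_len(nrow(lin)))),
                   file.path(dir, "lineage.yaml"))
  writeSelectionConfig(bundle$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write campaign outputs to a directory
#'
#' Per round: a read-count TSV; plus a round-summary table (round, input,
#' recovered, recovery rate) and a FASTA of the final round's most abundant
#' planted sequences. All files carry the seed and config hash.
#'
#' @param result a [CampaignResult-class].
#' @param dir output directory.
#' @param topN sequences in the final-round FASTA.
#' @return `dir`, invisibly.
#' @export
writeCampaignResult <- function(result, dir, topN = 10L) {
  stopifnot(is(result, "CampaignResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(dir, "config.yaml")
  writeSelectionConfig(result@config, cfgPath)
  prov <- c(seed = as.character(result@seed),
            config_md5 = configHash(cfgPath))
  for (t in result@readTables)
    writeReadCountTable(t, file.path(dir, sprintf("%s_round%d_counts.tsv",
                                                  result@library, t@round)),
                        provenance = prov)
  summ <- roundSummary(result)
  con <- file(file.path(dir, paste0(result@library, "_rounds.tsv")), "w")
  writeLines(paste0("# ", names(prov), ": ", prov), con)
  utils::write.table(summ, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  finalState <- result@rounds[[length(result@rounds)]]@postState
  sp <- speciesTable(finalState)
  sp <- sp[!is.na(sp$dna) & sp$count > 0, , drop = FALSE]
  if (nrow(sp)) {
    sp <- sp[order(-sp$count), , drop = FALSE]
    writeConstructFasta(utils::head(sp, topN),
                        file.path(dir, paste0(result@library, "_final_top.fasta")))
  }
  invisible(dir)
}
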