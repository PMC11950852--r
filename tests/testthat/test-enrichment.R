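# NGS-side enrichment analysis: counting, triage, dedup, clustering,
# trajectories and scatter tables.

test_that("read counting aggregates valid reads and tallies exclusions", {
  d <- LibraryDesign()
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E8", seed = 4)
  dna <- speciesTable(lib$state)$dna[1]
  pep <- speciesTable(lib$state)$peptide[1]

  tab <- countsFromReads(c(dna, dna, dna), design = d)
  expect_equal(unname(readCounts(tab)[pep]), 3)
  expect_equal(totalReads(tab), 3)

  # a read failing the AUG-start check is excluded with a tally
  bad <- sub("^ATG", "TTG", dna)
  tab2 <- countsFromReads(c(dna, bad), design = d)
  expect_equal(totalReads(tab2), 1)
  expect_equal(unname(tab2@metadata$excluded["no_start"]), 1)

  # FASTA file input
  path <- withr::local_tempfile(fileext = ".fasta")
  writeConstructFasta(stats::setNames(c(dna, dna), c("r1", "r2")), path)
  tab3 <- countsFromReads(path, design = d)
  expect_equal(totalReads(tab3), 2)

  # zero valid reads -> flagged empty table
  tab4 <- countsFromReads(c("TTTTTT"), design = d)
  expect_true(tab4@metadata$empty)
  expect_length(readCounts(tab4), 0)
})

test_that("sampled read counts sit inside multinomial envelopes", {
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E10", seed = 8)
  st <- lib$state
  truthFrac <- speciesTable(st)$count / totalMolecules(st)
  tab <- sampleReadCounts(st, depth = 1e4, seed = 1)
  obs <- readCounts(tab)[speciesTable(st)$peptide]
  obs[is.na(obs)] <- 0
  # 99.9% envelope: |obs - n p| <= 3.3 sqrt(n p (1-p)) + slack for tiny p
  n <- 1e4
  bound <- 3.3 * sqrt(n * truthFrac * (1 - truthFrac)) + 3
  expect_true(all(abs(as.numeric(obs) - n * truthFrac) <= bound))
})

test_that("triage applies the 2% rule with ranking, cap and scale invariance", {
  tab <- ReadCountTable(c(A = 5000, B = 1900, C = 100) * 1,
                        library = "x", round = 7)
  # pad totals to 1e5 via a background bin so fractions are explicit
  tabFull <- ReadCountTable(c(A = 5000, B = 1900, C = 100, bin = 93000),
                            isBackground = c(FALSE, FALSE, FALSE, TRUE))
  tri <- triagePositiveClones(tabFull, TriageConfig())
  expect_equal(tri$sequence, "A") # B at 1.9% fails the strict > 2% rule

  one <- ReadCountTable(c(ONLY = 500))
  expect_equal(triagePositiveClones(one, TriageConfig())$sequence, "ONLY")

  # ten sequences at 5% each: exactly maxClones returned, lexicographic ties
  ten <- ReadCountTable(stats::setNames(rep(500, 10), paste0("s", letters[1:10])),
                        library = "x")
  tri10 <- triagePositiveClones(ten, TriageConfig(maxClones = 7))
  expect_equal(nrow(tri10), 7)
  expect_equal(tri10$sequence, paste0("s", letters[1:7]))

  # invariant under uniform count scaling
  sc <- ReadCountTable(c(A = 5000, B = 1900, C = 100, bin = 93000) * 13,
                       isBackground = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(triagePositiveClones(sc, TriageConfig())$sequence, tri$sequence)

  expect_equal(nrow(triagePositiveClones(ReadCountTable(numeric()),
                                         TriageConfig())), 0)
})

test_that("the detection floor is the reciprocal read total", {
  expect_equal(detectionFloor(ReadCountTable(c(a = 99999, b = 1))), 1e-5)
  expect_equal(detectionFloor(1e5) * 100, 0.001) # 0.001%
  expect_equal(detectionFloor(1), 1)
  expect_equal(detectionFloor(2e6), 5e-7)
})

test_that("cross-library deduplication reproduces planted identity structure", {
  # all distinct
  res <- deduplicateAcrossLibraries(list(L1 = c(a = "AA"), L2 = c(b = "CC")))
  expect_equal(res$nUnique, 2)
  expect_equal(nrow(res$duplicatePairs), 0)

  # randomized fixture with k planted duplicates -> unique = n - k
  set.seed(31)
  for (rep in 1:5) {
    n <- 20; k <- sample(2:6, 1)
    seqs <- replicate(n - k, paste(sample(LETTERS[1:20], 10, TRUE), collapse = ""))
    dup <- sample(seqs, k)
    libs <- list(A = stats::setNames(seqs[1:10], paste0("A", 1:10)),
                 B = stats::setNames(c(seqs[11:(n - k)], dup),
                                     paste0("B", 1:(n - 10))))
    res <- deduplicateAcrossLibraries(libs)
    expect_equal(res$nUnique, n - k)
    expect_equal(nrow(res$duplicatePairs), k)
  }
})

test_that("family clustering recovers planted partitions exactly", {
  set.seed(19)
  bundle <- generateCampaignFixture(smallFixtureSpec(), seed = 19)
  truth <- do.call(rbind, lapply(bundle$libraries, `[[`, "truth"))
  truth <- truth[!duplicated(truth$peptide), ]
  cl <- clusterFamilies(stats::setNames(truth$peptide, truth$id))
  mem <- membership(cl)
  predicted <- ifelse(is.na(mem$family), mem$id, mem$family)
  expect_equal(randIndex(predicted[match(truth$id, mem$id)], truth$family), 1.0)

  # identical sequences collapse into one family whose consensus is the sequence
  same <- clusterFamilies(c(x = "AWAWAWAWAW", y = "AWAWAWAWAW", z = "AWAWAWAWAW"))
  expect_length(families(same), 1)
  expect_equal(unname(consensusMotifs(same)[1]), "AWAWAWAWAW")

  expect_error(clusterFamilies(c("AAA", "AAAA")), "equal length")
})

test_that("family clustering is invariant to input order", {
  set.seed(23)
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E14", seed = 23)
  peps <- stats::setNames(lib$truth$peptide, lib$truth$id)
  singles <- replicate(4, paste(sample(AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       15, TRUE), collapse = ""))
  names(singles) <- paste0("u", 1:4)
  peps <- c(peps, singles)
  a <- clusterFamilies(peps)
  b <- clusterFamilies(peps[sample(seq_along(peps))])
  expect_equal(families(a), families(b))
  expect_equal(singletons(a), singletons(b))
  expect_equal(consensusMotifs(a), consensusMotifs(b))
})

test_that("consensus positions follow the two-thirds cover rule", {
  peps <- c(m1 = "AAAA", m2 = "AAAC", m3 = "AACD", m4 = "AATE", m5 = "AAGF",
            m6 = "AAAA")
  cl <- clusterFamilies(peps, maxMismatchFraction = 0.75)
  cons <- cl@consensus[[1]]
  expect_equal(cons[[1]], "A")          # unanimous
  expect_equal(cons[[2]], "A")          # unanimous
  expect_equal(cons[[3]], c("A", "C"))  # 4/6 A + 1/6 C reaches 2/3 with 2 residues
  expect_equal(cons[[4]], "X")          # no 2-residue set covers 2/3
})

test_that("a peptide matching a planted consensus shares its conserved positions", {
  # family built on an F-II-like motif: conserved I/W/F/W at positions 1/3/6/11
  members <- c(p1 = "IAWAEFASPAWRFIT", p2 = "ISWNEFNSPNWRFIA",
               p3 = "IDWREFTSPNWAFIT")
  cl <- clusterFamilies(members)
  cons <- cl@consensus[[1]]
  query <- strsplit("ISWNEFNSPNWRFIT", "")[[1]] # known binder core
  for (pos in c(1, 3, 6, 11))
    expect_true(query[pos] %in% cons[[pos]] )
})

test_that("population trajectories are proper fractions that sum to one", {
  bundle <- generateCampaignFixture(smallFixtureSpec(2L), seed = 6)
  lib <- bundle$libraries$E10
  res <- runCampaign(lib$state, bundle$config, nRounds = 2, library = "E10",
                     seed = 6, budgets = lib$budgets)
  mem <- speciesTable(roundResults(res)[[2]]@postState)
  cl <- clusterFamilies(stats::setNames(lib$truth$peptide, lib$truth$id))
  tr <- populationTrajectories(readTables(res), cl)
  expect_true(all(tr$species >= 0 & tr$species <= 1))
  sums <- colSums(tr$families)
  expect_equal(unname(sums), rep(1, 2), tolerance = 1e-9)

  # a species absent in all rounds would have an all-zero row; single-species
  # library gives an all-one row
  one <- ReadCountTable(c(ONLY = 100), library = "z", round = 1)
  trOne <- populationTrajectories(list(one))
  expect_equal(unname(trOne$species["ONLY", ]), 1)

  mixed <- list(ReadCountTable(c(a = 1), library = "x"),
                ReadCountTable(c(a = 1), library = "y"))
  expect_error(populationTrajectories(mixed), "single library")
})

test_that("the kinetic scatter table flags best binders per library", {
  one <- kineticScatterTable(data.frame(id = "s", ka = 1e5, kd = 1e-2))
  expect_true(one$bestInLibrary)

  # ties in KD resolved toward the lower kd
  tie <- kineticScatterTable(data.frame(
    id = c("fast", "slow"), ka = c(1e6, 1e5), kd = c(1e-2, 1e-3)))
  expect_equal(tie$id[tie$bestInLibrary], "slow")

  # brute-force oracle over random panels
  set.seed(12)
  for (i in 1:5) {
    df <- data.frame(id = paste0("p", 1:5), ka = 10^runif(5, 4, 6),
                     kd = 10^runif(5, -3, -1), library = "L")
    out <- kineticScatterTable(df)
    expect_equal(out$id[out$bestInLibrary],
                 df$id[which.min(df$kd / df$ka)])
  }

  # missing kinetics listed but excluded from ranking
  mis <- kineticScatterTable(data.frame(
    id = c("ok", "na"), ka = c(1e5, NA), kd = c(1e-2, 1e-3)))
  expect_true(mis$kineticsMissing[2])
  expect_equal(mis$id[mis$bestInLibrary], "ok")
})

test_that("read-count tables round-trip through TSV", {
  tab <- ReadCountTable(c(AAA = 10, CCC = 5, bin001 = 100),
                        library = "E8", round = 3,
                        isBackground = c(FALSE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeReadCountTable(tab, path, provenance = c(seed = "7"))
  back <- readReadCountTable(path)
  expect_equal(readCounts(back), readCounts(tab))
  expect_equal(back@isBackground, tab@isBackground)
  expect_equal(back@library, "E8")
})
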