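# Fixture generator: determinism, sampling-loss structure, read sampling.

test_that("fixtures are bit-exact functions of (spec, seed)", {
  spec <- smallFixtureSpec()
  a <- generateCampaignFixture(spec, seed = 9)
  b <- generateCampaignFixture(spec, seed = 9)
  for (nm in names(a$libraries)) {
    expect_identical(speciesTable(a$libraries[[nm]]$state),
                     speciesTable(b$libraries[[nm]]$state))
    expect_identical(backgroundTable(a$libraries[[nm]]$state),
                     backgroundTable(b$libraries[[nm]]$state))
    expect_identical(a$libraries[[nm]]$truth, b$libraries[[nm]]$truth)
  }
  c <- generateCampaignFixture(spec, seed = 10)
  expect_false(identical(speciesTable(a$libraries$E14$state),
                         speciesTable(c$libraries$E14$state)))
})

test_that("rare families are probabilistically absent from small libraries", {
  spec <- smallFixtureSpec()
  # expected sampled variants: phi * diversity
  phi <- stats::setNames(spec@families$phi, spec@families$family)
  D6 <- spec@libraries$diversity[spec@libraries$name == "E6"]
  expect_lt(phi[["F-II"]] * D6, 0.01)  # essentially always lost from E6
  expect_gt(phi[["F-IV"]] * D6, 5)     # essentially always present in E6
  present <- sapply(1:10, function(s) {
    tr <- generatePlantedLibrary(spec, "E6", seed = s)$truth
    c(`F-II` = "F-II" %in% tr$family, `F-IV` = "F-IV" %in% tr$family)
  })
  expect_equal(sum(present["F-II", ]), 0)
  expect_equal(sum(present["F-IV", ]), 10)
  # all families present in the largest library
  tr14 <- generatePlantedLibrary(spec, "E14", seed = 1)$truth
  expect_true(all(c("F-I", "F-II", "F-III", "F-IV") %in% tr14$family))
})

test_that("planted copy numbers reflect budgets and frequencies", {
  spec <- smallFixtureSpec()
  lib <- generatePlantedLibrary(spec, "E14", seed = 2)
  st <- lib$state
  expect_equal(totalMolecules(st),
               spec@libraries$budgetRound1[spec@libraries$name == "E14"],
               tolerance = 1e-6)
  # family total frequency ~ phi (within Poisson noise)
  sp <- speciesTable(st)
  fIV <- sum(sp$count[sp$family == "F-IV"]) / totalMolecules(st)
  phiIV <- spec@families$phi[spec@families$family == "F-IV"]
  expect_equal(fIV, phiIV, tolerance = 0.05 * phiIV / fIV)
  expect_lt(abs(fIV / phiIV - 1), 0.05)
})

test_that("the two sampling lineages share no planted variant", {
  bundle <- generateCampaignFixture(smallFixtureSpec(), seed = 13)
  libsOf <- split(bundle$spec@libraries$name, bundle$spec@libraries$group)
  peps <- lapply(libsOf, function(nms)
    unlist(lapply(nms, function(nm) bundle$libraries[[nm]]$truth$peptide)))
  expect_length(intersect(peps[["1"]], peps[["2"]]), 0)
})

test_that("planted member kinetics sit near the family log-scale centres", {
  spec <- smallFixtureSpec()
  tr <- generatePlantedLibrary(spec, "E14", seed = 21)$truth
  for (f in unique(tr$family)) {
    centre <- spec@families[spec@families$family == f, ]
    dev <- abs(log10(tr$ka[tr$family == f]) - log10(centre$kaCenter))
    expect_true(all(dev < 4 * centre$jitter + 1e-9))
  }
})

test_that("read sampling is multinomial at the requested depth", {
  sp <- data.frame(id = c("a", "b"), peptide = c("AAAAA", "WWWWW"),
                   dna = NA_character_, ka = 1e5, kd = 1e-2, stickiness = 0,
                   family = NA_character_, count = c(5e5, 5e5),
                   stringsAsFactors = FALSE)
  st <- LibraryState(sp, emptyBackgroundTable())
  fracs <- vapply(1:30, function(s) {
    tab <- sampleReadCounts(st, depth = 1e5, seed = s)
    expect_equal(totalReads(tab), 1e5)
    unname(readCounts(tab)["AAAAA"]) / 1e5
  }, numeric(1))
  # species at true fraction 0.5 observed within 3 SE
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / 1e5) / sqrt(30))
  tab <- sampleReadCounts(st, depth = 1e5, seed = 1)
  expect_equal(detectionFloor(tab), 1e-5)
  expect_error(sampleReadCounts(LibraryState(), 100), "empty")
})

test_that("fixture bundles round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  bundle <- generateCampaignFixture(smallFixtureSpec(), seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "E14_planted.fasta")))
  expect_true(file.exists(file.path(dir, "consensus_motifs.tsv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  fa <- readConstructFasta(file.path(dir, "E14_planted.fasta"))
  sp <- speciesTable(bundle$libraries$E14$state)
  expect_equal(unname(fa[sp$id]), sp$dna)
  cfg <- readSelectionConfig(file.path(dir, "config.yaml"))
  expect_equal(cfg@captureEfficiency, bundle$config@captureEfficiency)
  expect_equal(cfg@seed, 3L)
})

test_that("ground-truth labels agree with sequence clustering at generator defaults", {
  bundle <- generateCampaignFixture(smallFixtureSpec(), seed = 17)
  truth <- do.call(rbind, lapply(bundle$libraries, `[[`, "truth"))
  truth <- truth[!duplicated(truth$peptide), ]
  cl <- clusterFamilies(stats::setNames(truth$peptide, truth$id))
  mem <- membership(cl)
  predicted <- ifelse(is.na(mem$family), mem$id, mem$family)
  expect_equal(randIndex(predicted[match(truth$id, mem$id)], truth$family), 1.0)
})
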