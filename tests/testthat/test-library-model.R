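# Library architecture, NNK sequence space and scale arithmetic.

test_that("NNK diversity matches brute-force codon enumeration and known scales", {
  # independent oracle: enumerate all codon pairs and count distinct strings
  codons <- nnkCodons()
  expect_length(codons, 32L)
  expect_false(anyDuplicated(codons) > 0)
  pairs <- outer(codons, codons, paste0)
  expect_equal(nnkTheoreticalDiversity(2), length(unique(as.vector(pairs))))
  expect_equal(nnkTheoreticalDiversity(0), 1)
  expect_equal(nnkTheoreticalDiversity(1), length(codons))
  expect_equal(signif(nnkTheoreticalDiversity(15), 2), 3.8e22)
  # strictly increasing in L
  divs <- vapply(0:6, nnkTheoreticalDiversity, numeric(1))
  expect_true(all(diff(divs) > 0))
  expect_error(nnkTheoreticalDiversity(-1), "nonnegative")
  expect_error(nnkTheoreticalDiversity(1.5), "integer")
})

test_that("ribosome and mRNA budgets are linear with the documented constants", {
  expect_equal(signif(ribosomeMolecules(TranslationBudget(1)), 2), 7.2e11)
  expect_equal(signif(ribosomeMolecules(TranslationBudget(5)), 2), 3.6e12)
  expect_equal(ribosomeMolecules(TranslationBudget(0)), 0)
  expect_equal(requiredMrnaPmol(TranslationBudget(150)), 180)
  expect_equal(requiredMrnaPmol(TranslationBudget(5)), 6)
  expect_equal(requiredMrnaPmol(TranslationBudget(2.5)), 3)
  # linearity and fixed molecules-per-pmol ratio across arbitrary budgets
  for (v in c(0.3, 2, 17, 150)) {
    b <- TranslationBudget(v, ribosomeConc = 0.8)
    expect_equal(ribosomeMolecules(b) / requiredMrnaPmol(b), 6.02214076e23 * 1e-12)
    expect_equal(ribosomeMolecules(b), v * ribosomeMolecules(TranslationBudget(1, 0.8)))
  }
  expect_error(TranslationBudget(-1), "nonnegative")
})

test_that("diversity suppression is the reciprocal recovery rate", {
  expect_equal(diversitySuppression(5e-6), 2e5)
  expect_equal(diversitySuppression(1), 1)
  expect_equal(diversitySuppression(2e-5), 5e4)
  expect_error(diversitySuppression(0))
  expect_error(diversitySuppression(1.5))
})

test_that("construct translation renders the initiator, linker and flags", {
  d0 <- LibraryDesign(randomCodonCount = 0)
  tr <- translateDisplayConstruct("AUG UGU UCC GGC GGA UUA ACU AAC", d0)
  expect_equal(tr$peptide, "yCSGGLTN")
  expect_true(tr$valid)

  # non-NNK codon in the random region is flagged (third base must be G/T)
  d1 <- LibraryDesign(randomCodonCount = 1)
  tr1 <- translateDisplayConstruct(paste0("ATG", "AAA", "TGT", d1@linkerDna), d1)
  expect_false(tr1$nnkValid[1])
  expect_false(tr1$valid)
  tr2 <- translateDisplayConstruct(paste0("ATG", "AAG", "TGT", d1@linkerDna), d1)
  expect_true(tr2$nnkValid[1])
  expect_true(tr2$valid)

  # amber TAG is a legal NNK codon but a stop-flagged position
  trStop <- translateDisplayConstruct(paste0("ATG", "TAG", "TGT", d1@linkerDna), d1)
  expect_true(trStop$nnkValid[1])
  expect_true(trStop$stopFlag)
  expect_false(trStop$valid)

  expect_error(translateDisplayConstruct("ATGA"), "multiple of 3")
  expect_error(translateDisplayConstruct("TTTAAA"), "AUG")
})

test_that("generated constructs translate to 17-residue cores without stops", {
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E8", seed = 5)
  sp <- speciesTable(lib$state)
  expect_gt(nrow(sp), 0)
  for (dna in sp$dna) {
    tr <- translateDisplayConstruct(dna)
    expect_true(tr$valid)
    expect_equal(nchar(tr$core), 17L) # initiator + 15 random + Cys
  }
  vec <- translateConstructSet(sp$dna)
  expect_true(all(vec$valid))
  expect_equal(vec$randomRegion, sp$peptide)
})

test_that("subset derivation thins diversity by the dilution factor", {
  parent <- LibrarySubset("P", 1e6)
  expect_equal(deriveSubset(parent, 1)@estimatedDiversity, 1e6)
  child <- deriveSubset(parent, 1e4)
  expect_equal(child@estimatedDiversity, 1e2)
  expect_equal(child@parent, "P")
  # two-step dilution equals one combined dilution in expected diversity
  ab <- deriveSubset(deriveSubset(parent, 50), 20)
  expect_equal(ab@estimatedDiversity, deriveSubset(parent, 1000)@estimatedDiversity)
  expect_error(deriveSubset(parent, 0.5), "dilutionFactor")
})

test_that("expected unique count follows the Poissonization formula", {
  expect_equal(expectedUniqueCount(1e6, 1e4), 1e4 * (1 - exp(-100)))
  expect_equal(expectedUniqueCount(10, 1e12), 10, tolerance = 1e-6) # n << D
  expect_equal(expectedUniqueCount(0, 10), 0)
})

test_that("the study lineage stores measured diversities verbatim as a forest", {
  subs <- librarySubsets()
  expect_equal(subs$E14@estimatedDiversity, 1.1e14)
  expect_equal(subs$E6@estimatedDiversity, 2.9e6)
  for (s in subs) {
    if (!is.na(s@parent)) {
      expect_true(s@parent %in% names(subs))
      expect_lte(s@estimatedDiversity, subs[[s@parent]]@estimatedDiversity)
      expect_equal(s@group, subs[[s@parent]]@group)
    }
  }
  expect_setequal(vapply(subs, methods::slot, character(1), "group"),
                  c("1", "1", "1", "2", "2"))
})

test_that("lineage configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLineageConfig(librarySubsets(), path)
  back <- readLineageConfig(path)
  expect_equal(names(back), names(librarySubsets()))
  expect_equal(back$E10@estimatedDiversity, 2.2e10)
  expect_equal(back$E10@parent, "E14")
})
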