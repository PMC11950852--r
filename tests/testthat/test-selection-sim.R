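# Round-by-round selection simulator: sampling, selection stages, PCR and
# full campaigns.

test_that("translation sampling is identity under budget and halves counts above it", {
  st <- twoSpeciesState(1e5, 1e-2, 1e5, 1e-2, count = 1e4)
  expect_identical(translationSampling(st, 1e9, seed = 1), st)

  # halving the pool halves each species in expectation; variance matches
  # binomial thinning over seeded replicates
  draws <- vapply(1:200, function(s)
    speciesTable(translationSampling(st, 1e4, seed = s))$count[1], numeric(1))
  expect_equal(mean(draws), 5e3, tolerance = 0.02)
  # multinomial component variance n*p*(1-p)
  expect_equal(stats::sd(draws), sqrt(1e4 * 0.5 * 0.5),
               tolerance = 3 / sqrt(200))
  # totals are exactly the budget
  tot <- totalMolecules(translationSampling(st, 1.2e4, seed = 3))
  expect_equal(tot, 1.2e4)
})

test_that("negative selection removes by stickiness", {
  clean <- twoSpeciesState(1e5, 1e-2, 1e5, 1e-2, count = 1e4, stickiness = 0)
  expect_equal(speciesTable(applyNegativeSelection(clean, SelectionConfig(), 1))$count,
               c(1e4, 1e4))
  sticky <- twoSpeciesState(1e5, 1e-2, 1e5, 1e-2, count = 1e4, stickiness = 1)
  expect_equal(speciesTable(applyNegativeSelection(sticky, SelectionConfig(), 1))$count,
               c(0, 0))
  mid <- twoSpeciesState(1e5, 1e-2, 1e5, 1e-2, count = 1e4, stickiness = 0.3)
  kept <- vapply(1:100, function(s)
    speciesTable(applyNegativeSelection(mid, SelectionConfig(), s))$count[1],
    numeric(1))
  expect_equal(mean(kept) / 1e4, 0.7, tolerance = 0.01)
})

test_that("positive selection survival follows the closed-form kinetic model", {
  cfg <- SelectionConfig()
  # saturating association, negligible dissociation, full capture -> p ~ 1
  ideal <- SelectionConfig(captureEfficiency = 1, nonspecificCarryover = 0)
  expect_equal(survivalProbability(1e9, 1e-12, 0, ideal), 1, tolerance = 1e-4)

  # survival decomposition: capture * fractionBound * washRetention + floor
  p <- survivalProbability(5.9e5, 4.2e-3, 2e-3, cfg)
  expect_equal(p,
    cfg@captureEfficiency *
      fractionBound(KineticParams(5.9e5, 4.2e-3), cfg@targetConc,
                    cfg@incubationTime) *
      washRetention(4.2e-3, cfg@nWashes, cfg@tWash) +
      2e-3 * cfg@nonspecificCarryover)

  # identical kinetics -> expected post-round ratio equals input ratio
  st <- twoSpeciesState(2e5, 1e-2, 2e5, 1e-2, count = 1e6)
  ratios <- vapply(1:50, function(s) {
    cnt <- speciesTable(applyPositiveSelection(st, cfg, seed = s)@postState)$count
    cnt[1] / sum(cnt)
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.02)

  # F-I vs F-III at equal input: simulated enrichment over 100 seeds matches
  # the closed-form survival ratio (wash term exp((45-4.2)e-3 * n * t) times
  # the association-term ratio)
  stF <- twoSpeciesState(5.9e5, 4.2e-3, 5.7e5, 45e-3, count = 1e6)
  rec <- vapply(1:100, function(s)
    speciesTable(applyPositiveSelection(stF, cfg, seed = s)@postState)$count,
    numeric(2))
  fbRatio <- fractionBound(KineticParams(5.9e5, 4.2e-3), cfg@targetConc,
                           cfg@incubationTime) /
    fractionBound(KineticParams(5.7e5, 45e-3), cfg@targetConc,
                  cfg@incubationTime)
  closedForm <- exp((45e-3 - 4.2e-3) * cfg@nWashes * cfg@tWash) * fbRatio
  expect_equal(mean(rec[1, ]) / mean(rec[2, ]), closedForm, tolerance = 0.05)

  # empty library -> flagged zero-recovery result
  res0 <- applyPositiveSelection(LibraryState(), cfg, seed = 1)
  expect_true(res0@empty)
  expect_equal(res0@recoveryRate, 0)
})

test_that("recovery rate is recovered over input and bounded", {
  cfg <- SelectionConfig()
  st <- twoSpeciesState(5.9e5, 4.2e-3, 5.7e5, 45e-3, count = 1e6,
                        withBackground = TRUE)
  res <- applyPositiveSelection(st, cfg, seed = 2)
  expect_equal(res@recoveryRate, res@recoveredTotal / res@inputTotal)
  expect_gte(res@recoveryRate, 0)
  expect_lte(res@recoveryRate, 1)
  expect_equal(res@inputTotal, totalMolecules(st))
})

test_that("PCR amplification preserves composition without mutation and conserves totals", {
  st <- twoSpeciesState(1e5, 1e-2, 1e5, 1e-2, count = 1e6,
                        withBackground = TRUE)
  cfg0 <- SelectionConfig(pcrMutationRate = 0)
  fracs <- vapply(1:50, function(s) {
    amp <- pcrAmplify(st, cfg0, targetTotal = 2e9, seed = s)
    expect_equal(totalMolecules(amp), 2e9)
    speciesTable(amp)$count[1] / totalMolecules(amp)
  }, numeric(1))
  expect_equal(mean(fracs), 1e6 / totalMolecules(st), tolerance = 0.02)
})

test_that("PCR mutant mass matches the analytic per-molecule expectation", {
  d <- LibraryDesign()
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E8", seed = 2)
  sp <- speciesTable(lib$state)[1, ]
  sp$count <- 1e6
  st <- LibraryState(sp, emptyBackgroundTable())
  cfg <- SelectionConfig() # 1e-4 per base per cycle, 15 cycles
  Lnt <- nchar(sp$dna)
  pExp <- 1 - (1 - cfg@pcrMutationRate)^(Lnt * cfg@pcrCycles)
  mutFrac <- vapply(1:40, function(s) {
    amp <- pcrAmplify(st, cfg, targetTotal = 1e6, seed = s,
                      minLineageSize = 1)
    spAmp <- speciesTable(amp)
    sum(spAmp$count[spAmp$id != sp$id]) / totalMolecules(amp)
  }, numeric(1))
  expect_equal(mean(mutFrac), pExp, tolerance = 0.05 * pExp / mean(mutFrac))
  expect_equal(mean(mutFrac), pExp, tolerance = 0.01)
})

test_that("a GAG->AAG point mutation yields the Glu->Lys replacement", {
  d1 <- LibraryDesign(randomCodonCount = 1)
  dna <- paste0("ATG", "GAG", "TGT", d1@linkerDna)
  expect_equal(translateDisplayConstruct(dna, d1)$randomRegion, "E")
  mut <- mutateDna(dna, 4, "A") # GAG -> AAG at codon position 1
  expect_equal(translateDisplayConstruct(mut, d1)$randomRegion, "K")
  # and GAT -> GGT gives Asp -> Gly
  dna2 <- paste0("ATG", "GAT", "TGT", d1@linkerDna)
  expect_equal(translateDisplayConstruct(mutateDna(dna2, 5, "G"), d1)$randomRegion,
               "G")
})

test_that("campaigns are seed-deterministic and conserve molecules per stage", {
  lib <- generatePlantedLibrary(smallFixtureSpec(), "E6", seed = 3)
  cfg <- SelectionConfig()
  r1 <- runCampaign(lib$state, cfg, nRounds = 3, seed = 11)
  r2 <- runCampaign(lib$state, cfg, nRounds = 3, seed = 11)
  expect_identical(roundSummary(r1), roundSummary(r2))
  for (k in 1:3)
    expect_identical(readCounts(readTables(r1)[[k]]),
                     readCounts(readTables(r2)[[k]]))
  r3 <- runCampaign(lib$state, cfg, nRounds = 3, seed = 12)
  expect_false(identical(roundSummary(r1), roundSummary(r3)))

  # no selection stage increases the molecule count
  st <- translationSampling(lib$state, 1e9, seed = 1)
  expect_lte(totalMolecules(st), totalMolecules(lib$state))
  neg <- applyNegativeSelection(st, cfg, seed = 1)
  expect_lte(totalMolecules(neg), totalMolecules(st))
  pos <- applyPositiveSelection(neg, cfg, seed = 1)
  expect_lte(totalMolecules(pos@postState), totalMolecules(neg))
  expect_true(all(speciesTable(pos@postState)$count >= 0))
})

test_that("a slow-kd species overtakes a fast-kd competitor round by round", {
  st <- twoSpeciesState(3e5, 4e-3, 3e5, 5e-2, count = 1e8,
                        withBackground = TRUE)
  cfg <- SelectionConfig(pcrMutationRate = 0)
  fracs <- sapply(1:10, function(s) {
    res <- runCampaign(st, cfg, nRounds = 4, seed = s, budgets = 1e10)
    vapply(roundResults(res), function(r) {
      cnt <- speciesTable(r@postState)$count
      cnt[1] / max(sum(cnt), 1)
    }, numeric(1))
  })
  # mean slow-kd share of the tracked pair increases every round
  expect_true(all(diff(rowMeans(fracs)) > 0))
})

test_that("a single-species library keeps a constant expected recovery rate", {
  sp <- data.frame(id = "only", peptide = "AAAAA", dna = NA_character_,
                   ka = 2e5, kd = 1e-2, stickiness = 0, family = NA_character_,
                   count = 1e8, stringsAsFactors = FALSE)
  cfg <- SelectionConfig(pcrMutationRate = 0)
  res <- runCampaign(LibraryState(sp, emptyBackgroundTable()), cfg,
                     nRounds = 3, seed = 5, budgets = 1e8)
  p <- survivalProbability(2e5, 1e-2, 0, cfg)
  expect_equal(recoveryRate(res), rep(p, 3), tolerance = 0.01)
})
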