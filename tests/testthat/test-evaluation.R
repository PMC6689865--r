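test_that("curation applies the averaging, span, bounds, and salt filters", {
  raw <- data.frame(
    smiles = c("CC(=O)O", "CCC(=O)O", "CCO", "CC(=O)O.[Na+]",
               "CS(=O)(=O)O", "CCCC(=O)O", "C[N+](=O)[O-]"),
    pka1 = c("4.0;4.5", "4.0;5.2", "16.5", "4.2", "-2.6", "30.0", "10"),
    moiety = c("carboxylic_acid", "carboxylic_acid", "alcohol",
               "carboxylic_acid", "sulfonate", "carboxylic_acid", "nitro"),
    stringsAsFactors = FALSE
  )
  cur <- curate(raw)
  rej <- attr(cur, "rejections")

  # replicates within 1.0 are averaged
  expect_equal(cur$pka1[cur$smiles == "CC(=O)O"], 4.25)
  # span > 1.0 discards
  expect_true("CCC(=O)O" %in% rej$smiles)
  expect_match(rej$reason[rej$smiles == "CCC(=O)O"], "span")
  # exception-listed moieties survive out-of-bounds values
  expect_true("CCO" %in% cur$smiles)        # alcohol above 15.7
  expect_true("CS(=O)(=O)O" %in% cur$smiles)  # sulfonate below -1.74
  # non-exception out-of-bounds and salts are discarded
  expect_true("CCCC(=O)O" %in% rej$smiles)
  expect_true("CC(=O)O.[Na+]" %in% rej$smiles)
  # nitro gets the sentinel pseudo-pKa
  expect_equal(cur$pka1[cur$moiety == "nitro"], -1000)
})

test_that("outcome classification follows the correct/excess/incorrect taxonomy", {
  cfg <- cfg_default
  expect_equal(classify_outcome(4.0, "deprotonated", cfg), "correct")
  expect_equal(classify_outcome(4.0, c("deprotonated", "protonated"), cfg),
               "excess")
  expect_equal(classify_outcome(7.0, "deprotonated", cfg), "incorrect")
  expect_equal(classify_outcome(7.0, c("deprotonated", "protonated"), cfg),
               "correct")
  expect_equal(classify_outcome(10.0, "protonated", cfg), "correct")
  expect_equal(classify_outcome(10.0, "deprotonated", cfg), "incorrect")
  # boundary pKa values require both states
  expect_equal(classify_outcome(6.4, c("deprotonated", "protonated"), cfg),
               "correct")
  expect_equal(classify_outcome(8.4, "protonated", cfg), "incorrect")
  expect_error(classify_outcome(7.0, character(0), cfg), "empty")

  # diprotic: required set built per dissociation over the ordered levels
  expect_equal(classify_outcome(c(2, 7), c("singly_deprotonated",
                                           "doubly_deprotonated"), cfg),
               "correct")
  expect_equal(classify_outcome(c(2, 3), "doubly_deprotonated", cfg),
               "correct")
  expect_equal(classify_outcome(c(2, 3), c("singly_deprotonated",
                                           "doubly_deprotonated"), cfg),
               "excess")
})

test_that("classification agrees with the explicit required-set oracle", {
  set.seed(13)
  state_sets <- list("deprotonated", "protonated",
                     c("deprotonated", "protonated"))
  for (k in 1:2000) {
    pka <- runif(1, -2, 16)
    emitted <- state_sets[[sample.int(3, 1)]]
    expect_identical(classify_outcome(pka, emitted, cfg_default),
                     oracle_outcome(pka, emitted, 6.4, 8.4))
  }
})

test_that("tally runs the engine and aggregates deterministically", {
  # all-correct construction: low-pKa acids are deprotonated and required so
  low <- make_moiety_compounds("sulfinic_acid", 12, seed = 3)
  t <- tally(low, rules, cfg_default, quiet = TRUE)
  expect_equal(t$n_total, 12L)
  expect_equal(unname(t$percent), c(100, 0, 0))

  # compounds drawn exactly at mu with an overlapping window are all correct
  at_mu <- make_moiety_compounds("phenol", 6, seed = 1)
  at_mu$pka1 <- 7.07
  t2 <- tally(at_mu, rules, cfg_default, quiet = TRUE)
  expect_equal(unname(t2$percent), c(100, 0, 0))

  # compounds whose labeled moiety the engine cannot find are excluded
  odd <- rbind(low[1:3, ],
               data.frame(smiles = "CCO", pka1 = 2, pka2 = NA,
                          moiety = "sulfinic_acid"))
  expect_message(t3 <- tally(odd, rules, cfg_default), "not detected")
  expect_equal(t3$n_total, 3L)
})

test_that("precision sweeps show the monotone excess/incorrect trends", {
  ds <- make_labeled_dataset(
    moieties = c("amine_primary", "carboxylic_acid", "phenol", "thiol",
                 "sulfonamide", "alcohol"),
    count_per_moiety = 15, seed = 21)
  sw <- sweep_precision(ds, rules, cfg_default,
                        n_values = c(0, 0.5, 1, 1.5, 2), quiet = TRUE)
  expect_equal(nrow(sw), 5L)
  expect_true(all(diff(sw$excess) >= -1e-9))
  expect_true(all(diff(sw$incorrect) <= 1e-9))
  expect_true(all(abs(sw$correct + sw$excess + sw$incorrect - 100) < 1e-6))
  # correct + excess never decreases as intervals widen
  expect_true(all(diff(sw$correct + sw$excess) >= -1e-9))
})

test_that("per-moiety cross-validation is seeded and reproducible", {
  low <- make_moiety_compounds("sulfinic_acid", 30, seed = 5)
  cv <- crossvalidate_moiety(low, cfg_default, k = 3, seed = 42)
  expect_equal(cv$correct_mean, 100)
  expect_equal(cv$correct_sd, 0)
  expect_equal(cv$excess_mean, 0)
  expect_equal(cv$incorrect_mean, 0)

  cv2 <- crossvalidate_moiety(low, cfg_default, k = 3, seed = 42)
  expect_identical(cv, cv2)
  cv3 <- crossvalidate_moiety(low, cfg_default, k = 3, seed = 43)
  expect_identical(cv$moiety, cv3$moiety)  # same structure, possibly same values

  # a wide-sigma moiety overlapping the window gives mostly excess, since
  # both states are emitted while single states are usually required
  ph <- make_moiety_compounds("phenol", 60, seed = 8)
  cvp <- crossvalidate_moiety(ph, cfg_default, k = 3, seed = 42)
  expect_gt(cvp$excess_mean, 50)
  expect_lt(cvp$incorrect_mean, 5)

  # moieties with fewer members than folds are skipped with a warning
  tiny <- rbind(low, make_moiety_compounds("phenol", 2, seed = 1))
  expect_warning(cv4 <- crossvalidate_moiety(tiny, cfg_default, k = 3,
                                             seed = 1), "fewer than")
  expect_false("phenol" %in% cv4$moiety)
})

test_that("labeled datasets round-trip through CSV and TSV", {
  ds <- make_moiety_compounds("thiol", 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pka_dataset(ds, f)
  back <- read_pka_dataset(f)
  expect_equal(back$smiles, ds$smiles)
  expect_equal(back$pka1, ds$pka1, tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pka_dataset(ds, f2, sep = "\t")
  expect_equal(read_pka_dataset(f2)$moiety, ds$moiety)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,value", "CCO,1"), bad)
  expect_error(read_pka_dataset(bad), "missing column")
})
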