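test_that("interval-overlap decision handles the three regimes and boundaries", {
  ph <- c(6.4, 8.4)
  expect_equal(decide_action(pka_range(7.07, 3.28, 1), ph), "both")
  expect_equal(decide_action(c(-1000, -1000), ph), "deprotonate")
  expect_equal(decide_action(c(10, 12), ph), "protonate")
  # boundary contact counts as overlap (the rule's inequalities are strict)
  expect_equal(decide_action(c(6.4, 6.4), ph), "both")
  expect_equal(decide_action(c(2, 6.4), ph), "both")
  expect_equal(decide_action(c(8.4, 12), ph), "both")
})

test_that("decision agrees with the brute-force overlap oracle", {
  set.seed(7)
  m <- 2000
  lo1 <- runif(m, -12, 18); hi1 <- lo1 + runif(m, 0, 10)
  lo2 <- runif(m, -2, 15); hi2 <- lo2 + runif(m, 0, 6)
  got <- decide_action(cbind(lo1, hi1), cbind(lo2, hi2))
  want <- vapply(seq_len(m), function(i) {
    oracle_action(c(lo1[i], hi1[i]), c(lo2[i], hi2[i]))
  }, character(1))
  expect_identical(got, want)
})

test_that("diprotic state selection respects dissociation order", {
  ph <- c(6.4, 8.4)
  # first dissociation below the window, second above: forced middle state
  expect_equal(diprotic_states(c(1, 3), c(10, 12), ph), "singly_deprotonated")
  # both overlap: all three forms
  expect_setequal(diprotic_states(c(5, 7), c(8, 9), ph),
                  c("fully_protonated", "singly_deprotonated",
                    "doubly_deprotonated"))
  # both entirely above: fully protonated only
  expect_equal(diprotic_states(c(9, 10), c(11, 12), ph), "fully_protonated")
  # both entirely below: doubly deprotonated only
  expect_equal(diprotic_states(c(1, 2), c(3, 4), ph), "doubly_deprotonated")
  # never an order-violating state, never empty
  set.seed(11)
  for (k in 1:200) {
    p1 <- sort(runif(2, -3, 14)); p2 <- p1 + runif(1, 0, 6)
    st <- diprotic_states(p1, p2, sort(runif(2, 0, 14)))
    expect_gte(length(st), 1L)
    expect_lte(length(st), 3L)
    expect_true(all(st %in% c("fully_protonated", "singly_deprotonated",
                              "doubly_deprotonated")))
  }
})

test_that("set_site_state applies absolute textbook edits", {
  ac <- detect_sites("CC(=O)O", rules)
  expect_equal(set_site_state("CC(=O)O", ac, "deprotonated"), "CC(=O)[O-]")
  expect_equal(set_site_state("CC(=O)O", ac, "protonated"), "CC(=O)O")
  # absolute semantics: the drawn input state is irrelevant
  expect_equal(set_site_state("CC(=O)[O-]", detect_sites("CC(=O)[O-]", rules),
                              "deprotonated"), "CC(=O)[O-]")

  tma <- detect_sites("CN(C)C", rules)
  expect_equal(set_site_state("CN(C)C", tma, "protonated"), "C[NH+](C)C")

  pyr <- detect_sites("c1ccncc1", rules)
  expect_equal(set_site_state("c1ccncc1", pyr, "protonated"), "c1cc[nH+]cc1")

  phos <- detect_sites("CP(=O)(O)O", rules)
  expect_equal(set_site_state("CP(=O)(O)O", phos, "doubly_deprotonated"),
               "CP(=O)([O-])[O-]")
  expect_equal(set_site_state("CP(=O)(O)O", phos, "fully_protonated"),
               "CP(=O)(O)O")
})

test_that("enumeration reproduces the worked reference cases", {
  # phenol: pKa interval straddles the window, two models
  ph <- enumerate_protomers("Oc1ccccc1", quiet = TRUE)
  expect_setequal(ph$protomer, c("Oc1ccccc1", "[O-]c1ccccc1"))

  # no ionizable site: the standardized input itself
  bz <- enumerate_protomers("c1ccccc1", quiet = TRUE)
  expect_equal(bz$protomer, "c1ccccc1")

  # lidocaine: two protomers differing at the tertiary amine
  lido <- enumerate_protomers("CCN(CC)CC(=O)Nc1c(C)cccc1C", quiet = TRUE)
  expect_equal(nrow(lido), 2L)
  expect_length(grep("[NH+]", lido$protomer, fixed = TRUE), 1L)

  # salicylic acid: carboxylate deprotonated in both, phenolic OH varies
  sal <- enumerate_protomers("OC(=O)c1ccccc1O", quiet = TRUE)
  expect_equal(nrow(sal), 2L)
  expect_true(all(grepl("C(=O)[O-]", sal$protomer, fixed = TRUE) |
                  grepl("O=C([O-])", sal$protomer, fixed = TRUE)))

  # phosphonate over a wide window: all three ionization states
  phos <- enumerate_protomers("CP(=O)(O)O",
                              config = protonation_config(0, 14),
                              quiet = TRUE)
  expect_setequal(phos$protomer,
                  c("CP(=O)(O)O", "CP(=O)([O-])O", "CP(=O)([O-])[O-]"))
})

test_that("drawn protonation state never affects the output set", {
  for (pair in list(c("CC(=O)O", "CC(=O)[O-]"),
                    c("CN", "C[NH3+]"),
                    c("c1ccncc1", "c1cc[nH+]cc1"))) {
    out <- enumerate_protomers(pair, quiet = TRUE)
    expect_equal(sort(out$protomer[out$input == pair[1]]),
                 sort(out$protomer[out$input == pair[2]]), label = pair[1])
  }
})

test_that("nitro groups are always emitted charge-separated and deprotonated", {
  for (cfg in list(protonation_config(), protonation_config(0, 14),
                   protonation_config(1, 2, precision = 3))) {
    out <- enumerate_protomers("c1ccccc1N(=O)=O", config = cfg, quiet = TRUE)
    expect_true(all(grepl("[N+]", out$protomer, fixed = TRUE)))
    expect_true(all(grepl("[O-]", out$protomer, fixed = TRUE)))
  }
})

test_that("protomer sets grow monotonically with the precision factor", {
  smi <- "NCC(=O)O"   # amine overlaps, carboxyl below window at n = 1
  sets <- lapply(c(0, 1, 2, 4), function(n) {
    enumerate_protomers(smi, config = protonation_config(precision = n),
                        quiet = TRUE)$protomer
  })
  for (k in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1L]]),
                label = paste("n step", k))
  }
})

test_that("outputs re-parse, contain no duplicates, and respect the cap", {
  out <- enumerate_protomers(make_polyprotic_molecule(3), quiet = TRUE)
  expect_equal(nrow(out), 8L)
  expect_false(any(duplicated(out$protomer)))
  expect_equal(parse_smiles(out$protomer), out$protomer)

  capped <- suppressMessages(enumerate_protomers(
    make_polyprotic_molecule(4),
    config = protonation_config(max_variants = 5)))
  expect_equal(nrow(capped), 5L)
  # truncation keeps the lexicographically first canonical strings
  full <- enumerate_protomers(make_polyprotic_molecule(4), quiet = TRUE)
  expect_equal(capped$protomer,
               sort(full$protomer, method = "radix")[1:5])
})

test_that("Henderson-Hasselbalch fractions match the worked examples", {
  expect_equal(round(100 * hh_fraction(4.0, 7.4, "deprotonated"), 2), 99.96)
  expect_equal(round(100 * hh_fraction(7.3, 7.4, "protonated"), 2), 44.27)
  expect_equal(hh_fraction(7, 7, "deprotonated"), 0.5)
  expect_equal(hh_fraction(7, 7, "protonated"), 0.5)
  # complementary forms sum to one
  expect_equal(hh_fraction(3:10, 7.4) + hh_fraction(3:10, 7.4, "protonated"),
               rep(1, 8))
})
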