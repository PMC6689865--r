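test_that("shipped table has 38 priority-ordered rules with expected anchors", {
  expect_equal(nrow(rules), 38L)
  expect_false(any(duplicated(rules$priority)))
  expect_true(all(diff(rules$priority) > 0))

  phenol <- rules[rules$name == "phenol", ]
  expect_equal(phenol$mu1, 7.07)
  expect_equal(phenol$sigma1, 3.28)

  nitro <- rules[rules$name == "nitro", ]
  expect_equal(nitro$mu1, -1000.0)
  expect_equal(nitro$sigma1, 0.0)

  # only the phosphate/phosphonate rules are diprotic, with two site atoms
  # and ordered dissociation constants
  dip <- rules[rules$class == "diprotic", ]
  expect_setequal(dip$name, c("phosphate", "phosphonate"))
  expect_true(all(lengths(dip$sites) == 2L))
  expect_true(all(dip$mu1 <= dip$mu2))
  expect_true(all(lengths(rules$sites[rules$class != "diprotic"]) == 1L))

  # the amide/amine containment pair is ordered for masking
  expect_lt(rules$priority[rules$name == "amide"],
            rules$priority[rules$name == "amine_primary"])
})

test_that("shipped table passes validation; corrupted tables are reported", {
  expect_length(validate_rule_table(rules), 0L)

  dup <- rules
  dup$priority[2] <- dup$priority[1]
  v <- validate_rule_table(dup)
  expect_true(any(grepl("duplicated priority", v)))
  expect_true(any(grepl(dup$name[1], v) & grepl(dup$name[2], v)))

  bad <- rules
  bad$smarts[bad$name == "phenol"] <- "C((("
  expect_true(any(grepl("phenol", validate_rule_table(bad))))

  neg <- rules
  neg$sigma1[neg$name == "thiol"] <- -1
  expect_true(any(grepl("thiol", validate_rule_table(neg))))
})

test_that("rule file parsing is strict about shape", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "phenol\t1\t[c][OX2H1]\t2\t7.07\t3.28"), f)
  t <- read_rule_table(f)
  expect_equal(nrow(t), 1L)
  expect_equal(t$sites[[1]], 2L)
  expect_equal(t$class, "acid")

  writeLines("phenol\t1\t[c][OX2H1]\t2\t7.07", f)
  expect_error(read_rule_table(f), "malformed")
  expect_error(read_rule_table(file.path(tempdir(), "absent-rules.tsv")),
               "not found")
})

test_that("pka_range widens monotonically in n and collapses at n = 0", {
  expect_equal(pka_range(7.07, 3.28, 1), c(3.79, 10.35))
  expect_equal(pka_range(5, 2, 0), c(5, 5))
  expect_equal(pka_range(-1000, 0, 1), c(-1000, -1000))
  expect_error(pka_range(5, 2, -1), "n must be")

  set.seed(4)
  for (k in 1:50) {
    mu <- runif(1, -5, 15)
    sd <- runif(1, 0, 4)
    n1 <- runif(1, 0, 3)
    n2 <- n1 + runif(1, 0, 3)
    inner <- pka_range(mu, sd, n1)
    outer <- pka_range(mu, sd, n2)
    expect_gte(inner[1], outer[1])
    expect_lte(inner[2], outer[2])
  }
})

test_that("configuration constructor enforces its invariants", {
  cfg <- protonation_config()
  expect_equal(cfg$ph_min, 6.4)
  expect_equal(cfg$ph_max, 8.4)
  expect_equal(cfg$precision, 1.0)
  expect_equal(cfg$max_variants, 128L)
  expect_error(protonation_config(8, 6), "ph_min")
  expect_error(protonation_config(precision = -0.1), "precision")
  expect_error(protonation_config(max_variants = 0), "max_variants")
})
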