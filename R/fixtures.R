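#' @title Synthetic fixture generators
#'
#' @description
#' Seeded generators for molecules and labeled pKa datasets with the
#' statistical structure the evaluation harness assumes, so every part of the
#' package is testable without any external database: each moiety has a
#' hand-written bank of template molecules guaranteed to contain exactly one
#' instance of that moiety, and pKa values are drawn from the rule's own
#' Normal(mu, sigma), truncated to the curation bounds unless the moiety is
#' exception-listed.
#' @name ionstate-fixtures
NULL

# Hand-written template bank: for every rule, molecules containing exactly
# one instance of that rule's substructure and no other ionizable group.
.moiety_templates <- list(
  nitro = c("C[N+](=O)[O-]", "CC[N+](=O)[O-]", "O=[N+]([O-])c1ccccc1",
            "Cc1ccc([N+](=O)[O-])cc1", "CC(C)[N+](=O)[O-]"),
  azide = c("N=[N+]=[N-]"),
  sulfate = c("COS(=O)(=O)O", "CCOS(=O)(=O)O", "CC(C)OS(=O)(=O)O",
              "CCCOS(=O)(=O)O"),
  sulfonate = c("CS(=O)(=O)O", "CCS(=O)(=O)O", "Cc1ccc(S(=O)(=O)O)cc1",
                "CC(C)S(=O)(=O)O", "CCCS(=O)(=O)O"),
  sulfinic_acid = c("CS(=O)O", "CCS(=O)O", "CCCS(=O)O", "CC(C)S(=O)O",
                    "O=S(O)c1ccccc1"),
  phosphate_diester = c("COP(=O)(O)OC", "CCOP(=O)(O)OCC", "COP(=O)(O)OCC"),
  phosphate = c("COP(=O)(O)O", "CCOP(=O)(O)O", "CC(C)OP(=O)(O)O",
                "CCCOP(=O)(O)O"),
  phosphonate_ester = c("CP(=O)(OC)O", "CCP(=O)(OC)O", "CP(=O)(OCC)O"),
  phosphinic_acid = c("CP(C)(=O)O", "CCP(C)(=O)O", "CCP(CC)(=O)O"),
  phosphonate = c("CP(=O)(O)O", "CCP(=O)(O)O", "CCCP(=O)(O)O",
                  "CC(C)P(=O)(O)O"),
  hydroxamic_acid = c("CC(=O)NO", "CCC(=O)NO", "O=C(NO)c1ccccc1"),
  thioic_acid = c("CC(=O)S", "CCC(=O)S", "O=C(S)c1ccccc1"),
  peracid = c("CC(=O)OO", "CCC(=O)OO", "O=C(OO)c1ccccc1"),
  benzoic_acid = c("OC(=O)c1ccccc1", "Cc1ccc(C(=O)O)cc1",
                   "OC(=O)c1ccc(Cl)cc1", "OC(=O)c1ccc(F)cc1",
                   "COc1ccc(C(=O)O)cc1", "CCc1ccc(C(=O)O)cc1"),
  carboxylic_acid = c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O",
                      "OC(=O)CC1CCCCC1", "CCCC(=O)O", "CCCCC(=O)O"),
  imide = c("O=C1CCC(=O)N1", "CC(=O)NC(C)=O", "O=C1CCCC(=O)N1"),
  amide_electronegative = c("CC(=O)NN", "CC(=O)NCl", "CCC(=O)NN",
                            "CC(=O)N(C)N"),
  amide = c("CC(=O)N", "CC(=O)NC", "CCC(=O)N", "CC(=O)N(C)C",
            "O=C(N)c1ccccc1"),
  sulfonamide = c("CS(=O)(=O)N", "CCS(=O)(=O)N", "CS(=O)(=O)NC",
                  "Cc1ccc(S(N)(=O)=O)cc1", "CCCS(=O)(=O)N"),
  tetrazole = c("c1nnn[nH]1", "Cc1nnn[nH]1", "CCc1nnn[nH]1"),
  aromatic_n_protonated = c("c1cc[nH]c1", "c1ccc2[nH]ccc2c1", "Cc1cc[nH]c1"),
  aromatic_n_unprotonated = c("c1ccncc1", "Cc1ccncc1", "CCc1ccncc1",
                              "c1ccc2ncccc2c1", "Cc1ccccn1"),
  thiophenol = c("Sc1ccccc1", "Cc1ccc(S)cc1", "Sc1ccc(Cl)cc1"),
  thiol = c("CCS", "CCCS", "CC(C)S", "SCC1CCCCC1", "SC1CCCCC1", "CCCCS"),
  phenol = c("Oc1ccccc1", "Cc1ccc(O)cc1", "Oc1ccc(Cl)cc1", "Oc1ccc(F)cc1",
             "COc1ccc(O)cc1", "CCc1ccc(O)cc1", "CC(C)c1ccc(O)cc1"),
  peroxide = c("COO", "CCOO", "CC(C)OO"),
  enol_conjugated_ketone = c("CC(=O)C=C(C)O", "CC(=O)C=CO", "O=CC=CO"),
  vinyl_alcohol = c("C=CO", "CC=CO", "C=C(C)O"),
  alcohol = c("CCO", "CC(C)O", "CCCO", "OCC1CCCCC1", "OC1CCCCC1",
              "CC(C)(C)O", "CCCCO"),
  guanidine = c("NC(=N)N", "CNC(=N)N", "NC(=N)NC", "CNC(=N)NC"),
  amidine = c("CC(=N)N", "CCC(=N)N", "NC(=N)c1ccccc1"),
  aniline_primary = c("Nc1ccccc1", "Nc1ccc(C)cc1", "Nc1ccc(Cl)cc1",
                      "Nc1ccc(F)cc1", "Nc1ccc(CC)cc1"),
  aniline_secondary = c("CNc1ccccc1", "CCNc1ccccc1", "CNc1ccc(C)cc1"),
  aniline_tertiary = c("CN(C)c1ccccc1", "CCN(C)c1ccccc1",
                       "CCN(CC)c1ccccc1"),
  hydroxylamine = c("NO", "NOC", "NOCC"),
  amine_primary = c("CCN", "CCCN", "CC(C)N", "NC1CCCCC1", "NCC1CCCCC1",
                    "CC(C)(C)N", "CCCCN"),
  amine_secondary = c("CNCC", "CCNCC", "C1CCNCC1", "CNCCC", "CC(C)NC"),
  amine_tertiary = c("CN(C)C", "CCN(CC)CC", "CN1CCCCC1", "CCN(C)C")
)

#' Moieties with a synthetic template bank
#'
#' @return character vector of rule names for which
#'   [make_moiety_compounds()] has molecule templates.
#' @export
fixture_moieties <- function() names(.moiety_templates)

#' Generate labeled compounds for one moiety
#'
#' Emits `count` compounds whose SMILES is drawn cyclically from the moiety's
#' template bank and whose pKa value(s) are drawn from the rule's
#' Normal(mu, sigma), truncated by rejection to the curation bounds
#' `[-1.74, 15.7]` unless the moiety is exception-listed (see [curate()]).
#' Diprotic moieties draw both dissociation constants (ordered). The nitro
#' moiety always carries the sentinel pseudo-pKa -1000. Deterministic for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param moiety a rule name with a template bank (see [fixture_moieties()]).
#' @param count number of compounds (>= 1).
#' @param seed integer seed.
#' @param rules a [rule_table][read_rule_table] supplying mu/sigma.
#' @return data.frame with columns `smiles`, `pka1`, `pka2`, `moiety`.
#' @examples
#' make_moiety_compounds("phenol", 5, seed = 7)
#' @export
make_moiety_compounds <- function(moiety, count, seed = 1L,
                                  rules = load_default_rules()) {
  stopifnot(length(moiety) == 1L, count >= 1L)
  templates <- .moiety_templates[[moiety]]
  if (is.null(templates)) {
    stop("no template bank for moiety '", moiety, "'; see fixture_moieties()",
         call. = FALSE)
  }
  idx <- match(moiety, rules$name)
  if (is.na(idx)) stop("moiety '", moiety, "' not in rule table",
                       call. = FALSE)
  rule <- rules[idx, , drop = FALSE]
  exceptions <- c("sulfonate", "sulfate", "alcohol", "amide",
                  "aromatic_n_protonated")
  truncate <- !(moiety %in% exceptions)
  draw <- function(mu, sigma, n) {
    if (sigma == 0) return(rep(mu, n))
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mu, sigma)
      if (truncate) x <- x[x >= -1.74 & x <= 15.7]
      out <- c(out, x)
    }
    out[seq_len(n)]
  }
  with_seed(seed, {
    if (moiety == "nitro") {
      pka1 <- rep(-1000.0, count)
      pka2 <- rep(NA_real_, count)
    } else if (rule$class == "diprotic") {
      p1 <- draw(rule$mu1, rule$sigma1, count)
      p2 <- draw(rule$mu2, rule$sigma2, count)
      pka1 <- pmin(p1, p2)
      pka2 <- pmax(p1, p2)
    } else {
      pka1 <- draw(rule$mu1, rule$sigma1, count)
      pka2 <- rep(NA_real_, count)
    }
    data.frame(
      smiles = rep_len(templates, count),
      pka1 = pka1, pka2 = pka2, moiety = moiety,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a multi-moiety labeled dataset
#'
#' Convenience wrapper drawing `count_per_moiety` compounds for each requested
#' moiety with per-moiety derived seeds.
#'
#' @param moieties character vector of rule names (default: a drug-like
#'   selection of ten monoprotic moieties).
#' @param count_per_moiety compounds per moiety.
#' @param seed integer seed.
#' @inheritParams make_moiety_compounds
#' @return data.frame with columns `smiles`, `pka1`, `pka2`, `moiety`.
#' @export
make_labeled_dataset <- function(moieties = c(
                                   "amine_primary", "amine_secondary",
                                   "amine_tertiary", "carboxylic_acid",
                                   "benzoic_acid", "phenol", "sulfonamide",
                                   "thiol", "alcohol", "sulfinic_acid",
                                   "guanidine", "aromatic_n_unprotonated"),
                                 count_per_moiety = 45L, seed = 1L,
                                 rules = load_default_rules()) {
  parts <- lapply(seq_along(moieties), function(i) {
    make_moiety_compounds(moieties[i], count_per_moiety,
                          seed = seed + i, rules = rules)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Linear polyamine with i independent ionizable sites
#'
#' Builds a chain secondary polyamine with `i` well-separated secondary amine
#' sites. Segment lengths grow along the chain and the two chain ends differ,
#' so the molecule has no symmetry and every combination of per-site states
#' is a distinct protomer. Each site's rule interval overlaps the default pH
#' window, so default enumeration yields exactly `2^i` protomers (up to the
#' output cap).
#'
#' @param i number of amine sites (1 to 7).
#' @return a SMILES string.
#' @examples
#' make_polyprotic_molecule(3)   # enumerates to 8 protomers at defaults
#' @export
make_polyprotic_molecule <- function(i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > 7L) {
    stop("i must be an integer in 1..7", call. = FALSE)
  }
  inner <- if (i >= 2L) {
    paste(vapply(seq(2L, i), function(j) paste0(strrep("C", j), "N"),
                 character(1)), collapse = "")
  } else ""
  paste0("CN", inner, "CC")
}
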