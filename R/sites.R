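#' Detect ionizable sites by prioritized SMARTS matching with atom masking
#'
#' Rules are applied in priority order. Each substructure match whose atoms
#' are all still unclaimed yields one ionizable site per ionizable-atom
#' position of the rule and claims every atom of the match; claimed atoms are
#' invisible to all later (lower-priority) rules, so e.g. an amide nitrogen is
#' never additionally reported as an amine. Duplicate matches of the same rule
#' on the same atom set (symmetric orientations) are collapsed; matches of the
#' same rule on disjoint atoms each yield an independent site.
#'
#' @param smiles a single SMILES string, or a character vector (a list of
#'   site sets is then returned).
#' @param rules a [rule_table][read_rule_table] (default: the shipped table).
#' @param quiet suppress parse messages.
#' @return for a single input, a `site_set`: data.frame with columns `rule`,
#'   `priority`, `class`, `atom` (1-based index of the ionizable atom in the
#'   standardized molecule; two rows share a match for diprotic rules, see
#'   column `site_no`), `site_no`, and `match_atoms` (list column), ordered by
#'   (priority, atom), with the standardized canonical SMILES in attribute
#'   `molecule`. Unparseable input raises an error. For vector input, a named
#'   list of site sets (`NULL` for unparseable records, with a message).
#' @examples
#' \dontrun{
#' detect_sites("CC(=O)N")        # one amide site; no amine reported
#' detect_sites("NCC(=O)O")       # amine + carboxylic acid
#' }
#' @export
detect_sites <- function(smiles, rules = load_default_rules(), quiet = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- backend_match(smiles, rules)
  sets <- lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) {
      if (length(smiles) == 1L) {
        stop("SMILES parse error: ", r$error, call. = FALSE)
      }
      if (!quiet) message("skipping unparseable SMILES: ", smiles[i])
      return(NULL)
    }
    mask_sites(r$matches, rules, molecule = r$smiles)
  })
  if (length(smiles) == 1L) sets[[1L]] else stats::setNames(sets, smiles)
}

# Priority masking over raw per-rule matches (list of integer matrices of
# 1-based molecule-atom indices, one row per match). Returns a site_set.
mask_sites <- function(matches, rules, molecule) {
  claimed <- integer(0)
  out <- vector("list", nrow(rules))
  for (k in seq_len(nrow(rules))) {
    m <- matches[[rules$name[k]]]
    if (is.null(m) || nrow(m) == 0L) next
    # deterministic order + symmetric-duplicate collapse by sorted atom set
    keys <- apply(m, 1L, function(row) paste(sort(row), collapse = ","))
    m <- m[!duplicated(keys), , drop = FALSE]
    keys <- keys[!duplicated(keys)]
    m <- m[order(keys), , drop = FALSE]
    rows <- list()
    for (j in seq_len(nrow(m))) {
      atoms <- m[j, ]
      if (any(atoms %in% claimed)) next
      claimed <- c(claimed, atoms)
      site_pos <- rules$sites[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        rule = rules$name[k],
        priority = rules$priority[k],
        class = rules$class[k],
        atom = atoms[site_pos],
        site_no = seq_along(site_pos),
        match_id = j,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$match_atoms <-
        rep(list(as.integer(atoms)), length(site_pos))
    }
    if (length(rows)) out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(0), priority = integer(0),
               class = character(0), atom = integer(0), site_no = integer(0),
               match_id = integer(0),
               match_atoms = I(list()), stringsAsFactors = FALSE)
  sites <- sites[order(sites$priority, sites$atom), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "molecule") <- molecule
  class(sites) <- c("site_set", "data.frame")
  sites
}

#' @export
print.site_set <- function(x, ...) {
  cat("Ionizable sites of ", attr(x, "molecule"), ":\n", sep = "")
  if (nrow(x) == 0L) {
    cat("  (none)\n")
  } else {
    show <- data.frame(rule = x$rule, class = x$class, atom = x$atom,
                       site_no = x$site_no)
    print.data.frame(show, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Count raw (unmasked) matches of one rule in a molecule
#'
#' Diagnostic helper: the number of distinct atom sets matched by a single
#' rule's SMARTS, before any priority masking.
#'
#' @param smiles a single SMILES string.
#' @param rule a rule name present in `rules`, or a single-row subset of a
#'   rule table.
#' @param rules a [rule_table][read_rule_table] used to resolve `rule` when it
#'   is given by name.
#' @return integer count.
#' @examples
#' \dontrun{
#' count_rule_matches("Oc1ccc(O)cc1", "phenol")   # 2
#' }
#' @export
count_rule_matches <- function(smiles, rule, rules = load_default_rules()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.character(rule)) {
    stopifnot(length(rule) == 1L)
    idx <- match(rule, rules$name)
    if (is.na(idx)) stop("unknown rule: ", rule, call. = FALSE)
    rule <- rules[idx, , drop = FALSE]
  }
  res <- backend_match(smiles, rule)[[1L]]
  if (!isTRUE(res$ok)) stop("SMILES parse error: ", res$error, call. = FALSE)
  m <- res$matches[[rule$name[1L]]]
  if (is.null(m)) return(0L)
  keys <- apply(m, 1L, function(row) paste(sort(row), collapse = ","))
  length(unique(keys))
}
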