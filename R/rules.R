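#' Read an ionizable-substructure rule table
#'
#' Parses a tab-separated rule file into a `rule_table`. Each non-comment line
#' is `name<TAB>priority<TAB>SMARTS<TAB>site_indices<TAB>mu1<TAB>sigma1` with
#' an optional `<TAB>mu2<TAB>sigma2` pair marking a diprotic site (first-then-
#' second dissociation). `site_indices` are 1-based positions of the ionizable
#' atom(s) within the SMARTS pattern, comma-separated for diprotic rules.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to a UTF-8 tab-separated rule file.
#' @return a `rule_table`: a data.frame with columns `name`, `priority`,
#'   `smarts`, `sites` (list of integer vectors), `mu1`, `sigma1`, `mu2`,
#'   `sigma2` (`NA` for monoprotic rules), and `class` (`"acid"`, `"base"`, or
#'   `"diprotic"`), ordered by priority.
#' @seealso [load_default_rules()], [validate_rule_table()]
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) {
    stop("rule file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("rule file contains no rules: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L & nf != 8L)) {
    bad <- which(nf != 6L & nf != 8L)[1L]
    stop("malformed rule line ", bad, " in ", path,
         " (expected 6 or 8 tab-separated fields, found ", nf[bad], ")",
         call. = FALSE)
  }
  fld <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(i, required = TRUE) {
    vapply(parts, function(p) {
      if (length(p) >= i) as.numeric(p[[i]]) else NA_real_
    }, numeric(1))
  }
  tab <- data.frame(
    name = fld(1),
    priority = as.integer(fld(2)),
    smarts = fld(3),
    stringsAsFactors = FALSE
  )
  tab$sites <- lapply(parts, function(p) {
    as.integer(strsplit(p[[4]], ",", fixed = TRUE)[[1]])
  })
  tab$mu1 <- num(5)
  tab$sigma1 <- num(6)
  tab$mu2 <- num(7)
  tab$sigma2 <- num(8)
  tab$class <- ifelse(!is.na(tab$mu2), "diprotic",
                      ifelse(tab$name %in% .base_rules, "base", "acid"))
  tab <- tab[order(tab$priority), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("rule_table", "data.frame")
  tab
}

# Rules whose ionizable atom is a basic nitrogen (protonated form carries +1);
# every other monoprotic rule is an acid (deprotonated form carries -1).
.base_rules <- c(
  "aromatic_n_unprotonated", "guanidine", "amidine",
  "aniline_primary", "aniline_secondary", "aniline_tertiary",
  "hydroxylamine", "amine_primary", "amine_secondary", "amine_tertiary"
)

# Rules whose ionizable atom is an aromatic nitrogen: implicit-valence rules
# cannot restore ring hydrogens, so edits carry an explicit H count.
.aromatic_n_rules <- c(
  "tetrazole", "aromatic_n_protonated", "aromatic_n_unprotonated"
)

#' Load the shipped 38-rule ionizable-substructure table
#'
#' The default table covers the ionizable moieties handled by the engine
#' (amines, anilines, carboxylic and phenyl-carboxylic acids, phenols,
#' thiols, sulfonamides, amides and N-electronegative amides, imides,
#' hydroxamic and thioic acids, sulfinic/sulfonic/sulfate oxyacids, the
#' phosphorus oxyacid family including diprotic phosphates and phosphonates,
#' guanidines/amidines, aromatic nitrogens, azides, nitro groups, alcohols,
#' enols, peroxides, and tetrazoles), in decreasing priority order so that
#' larger high-priority substructures (e.g. amides) mask the smaller groups
#' they contain (e.g. amines). The nitro rule carries the sentinel mean
#' -1000 so its oxygens are always deprotonated.
#'
#' @return a [rule_table][read_rule_table] with 38 rows.
#' @examples
#' \dontrun{
#' rules <- load_default_rules()
#' nrow(rules)                         # 38
#' rules[rules$name == "phenol", c("mu1", "sigma1")]
#' }
#' @export
load_default_rules <- function() {
  path <- system.file("extdata", "ionizable_substructures.tsv",
                      package = "ionstate")
  if (!nzchar(path)) {
    stop("bundled rule file 'extdata/ionizable_substructures.tsv' is missing;",
         " the ionstate installation is corrupt", call. = FALSE)
  }
  read_rule_table(path)
}

#' @export
print.rule_table <- function(x, ...) {
  cat("Ionizable-substructure rule table: ", nrow(x), " rules\n", sep = "")
  cat("  acids: ", sum(x$class == "acid"),
      ", bases: ", sum(x$class == "base"),
      ", diprotic: ", sum(x$class == "diprotic"), "\n", sep = "")
  show <- data.frame(name = x$name, priority = x$priority,
                     mu = x$mu1, sigma = x$sigma1, class = x$class)
  print.data.frame(show, row.names = FALSE, ...)
  invisible(x)
}

#' Empirical pKa interval of a rule point
#'
#' Builds the plausible-pKa interval `[mu - n*sigma, mu + n*sigma]` used by
#' the protonation decision, where `n` is the pKa precision factor.
#'
#' @param mean empirical pKa mean (mu) of the moiety.
#' @param sd empirical pKa standard deviation (sigma, >= 0).
#' @param n pKa precision factor (dimensionless, >= 0; default 1).
#' @return numeric vector `c(lo, hi)`.
#' @examples
#' pka_range(7.07, 3.28, 1)   # phenol at n = 1: [3.79, 10.35]
#' @export
pka_range <- function(mean, sd, n = 1.0) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n),
            length(n) == 1L)
  if (any(sd < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (is.na(n) || n < 0) stop("precision factor n must be >= 0", call. = FALSE)
  c(mean - n * sd, mean + n * sd)
}

#' Validate a rule table
#'
#' Checks the structural invariants of a [rule_table][read_rule_table]:
#' unique priorities, parseable SMARTS, site indices within the pattern,
#' non-negative sigmas, and ordered dissociation constants (mu1 <= mu2) for
#' diprotic rules. Violations are returned as data, not raised.
#'
#' @param table a `rule_table`.
#' @return character vector of violation messages (empty if the table is
#'   valid), each naming the offending rule(s).
#' @export
validate_rule_table <- function(table) {
  violations <- character(0)
  dup <- table$priority[duplicated(table$priority)]
  for (p in unique(dup)) {
    nms <- table$name[table$priority == p]
    violations <- c(violations, paste0(
      "duplicated priority ", p, ": ", paste(nms, collapse = ", ")))
  }
  if (any(is.na(table$sigma1) | table$sigma1 < 0)) {
    bad <- table$name[is.na(table$sigma1) | table$sigma1 < 0]
    violations <- c(violations,
                    paste0("negative or missing sigma: ",
                           paste(bad, collapse = ", ")))
  }
  dip <- !is.na(table$mu2)
  bad_order <- dip & table$mu1 > table$mu2
  if (any(bad_order)) {
    violations <- c(violations, paste0(
      "diprotic mu1 > mu2 (dissociations out of order): ",
      paste(table$name[bad_order], collapse = ", ")))
  }
  bad_sig2 <- dip & (is.na(table$sigma2) | table$sigma2 < 0)
  if (any(bad_sig2)) {
    violations <- c(violations, paste0(
      "negative or missing sigma2: ",
      paste(table$name[bad_sig2], collapse = ", ")))
  }
  n_sites <- lengths(table$sites)
  want <- ifelse(dip, 2L, 1L)
  if (any(n_sites != want)) {
    bad <- table$name[n_sites != want]
    violations <- c(violations, paste0(
      "site count does not match pKa point count: ",
      paste(bad, collapse = ", ")))
  }
  # SMARTS parseability and site-index bounds need the chemistry backend:
  # probe each pattern against a trivial molecule.
  probe <- tryCatch(
    backend_match("C", data.frame(name = table$name, smarts = table$smarts,
                                  stringsAsFactors = FALSE)),
    error = function(e) conditionMessage(e)
  )
  if (is.character(probe)) {
    # backend reports the first invalid SMARTS by rule name
    violations <- c(violations, probe)
  }
  n_pattern_atoms <- vapply(table$smarts, smarts_atom_count, integer(1))
  too_big <- mapply(function(s, np) any(s < 1L | s > np),
                    table$sites, n_pattern_atoms)
  if (any(too_big)) {
    violations <- c(violations, paste0(
      "site index outside SMARTS pattern: ",
      paste(table$name[too_big], collapse = ", ")))
  }
  violations
}

# Count the atoms of a SMARTS pattern without a chemistry call: one atom per
# bracket expression (ignoring nested recursive-SMARTS brackets) plus bare
# organic-subset atom symbols outside brackets.
smarts_atom_count <- function(smarts) {
  chars <- strsplit(smarts, "", fixed = TRUE)[[1]]
  depth <- 0L
  n <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      if (depth == 0L) n <- n + 1L
      depth <- depth + 1L
    } else if (ch == "]") {
      depth <- depth - 1L
    } else if (depth == 0L) {
      two <- paste0(ch, if (i < length(chars)) chars[i + 1L] else "")
      if (two %in% c("Cl", "Br")) {
        n <- n + 1L
        i <- i + 1L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                           "b", "c", "n", "o", "p", "s")) {
        n <- n + 1L
      }
    }
    i <- i + 1L
  }
  n
}

#' Protonation run configuration
#'
#' @param ph_min minimum pH of the window to enumerate for (default 6.4).
#' @param ph_max maximum pH (default 8.4).
#' @param precision pKa precision factor `n` multiplying each rule's sigma
#'   (default 1.0); larger values widen every pKa interval, so more sites are
#'   emitted in both states.
#' @param max_variants cap on the number of protomers returned per input
#'   molecule (default 128 = 2^7); enumerations beyond the cap are truncated
#'   deterministically, keeping the lexicographically first canonical SMILES.
#' @return object of class `protonation_config`.
#' @export
protonation_config <- function(ph_min = 6.4, ph_max = 8.4, precision = 1.0,
                               max_variants = 128L) {
  stopifnot(is.numeric(ph_min), is.numeric(ph_max), is.numeric(precision),
            length(ph_min) == 1L, length(ph_max) == 1L,
            length(precision) == 1L)
  if (ph_min > ph_max) stop("ph_min must be <= ph_max", call. = FALSE)
  if (precision < 0) stop("precision factor must be >= 0", call. = FALSE)
  max_variants <- as.integer(max_variants)
  if (is.na(max_variants) || max_variants < 1L) {
    stop("max_variants must be a positive integer", call. = FALSE)
  }
  structure(list(ph_min = ph_min, ph_max = ph_max, precision = precision,
                 max_variants = max_variants),
            class = "protonation_config")
}

#' @export
print.protonation_config <- function(x, ...) {
  cat(sprintf(
    "Protonation config: pH [%.2f, %.2f], precision n = %.2f, cap %d\n",
    x$ph_min, x$ph_max, x$precision, x$max_variants))
  invisible(x)
}
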