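#' Interval-overlap protonation decision
#'
#' Compares a moiety's plausible-pKa interval with the pH window: if the pKa
#' interval lies entirely below the window the site is deprotonated; entirely
#' above, protonated; otherwise (any overlap, including boundary contact) both
#' states are emitted.
#'
#' @param pka pKa interval: numeric `c(lo, hi)` (see [pka_range()]) or a
#'   two-column matrix for row-wise vectorized use.
#' @param ph pH interval: numeric `c(ph_min, ph_max)` or a two-column matrix.
#' @return character `"deprotonate"`, `"protonate"`, or `"both"` (vector for
#'   matrix input).
#' @examples
#' decide_action(pka_range(7.07, 3.28, 1), c(6.4, 8.4))   # "both"
#' decide_action(c(-1000, -1000), c(6.4, 8.4))            # "deprotonate"
#' @export
decide_action <- function(pka, ph) {
  pka <- as_interval(pka)
  ph <- as_interval(ph)
  if (nrow(pka) != nrow(ph)) {
    if (nrow(ph) == 1L) ph <- ph[rep(1L, nrow(pka)), , drop = FALSE]
    else if (nrow(pka) == 1L) pka <- pka[rep(1L, nrow(ph)), , drop = FALSE]
    else stop("pka and ph must have compatible lengths", call. = FALSE)
  }
  ifelse(pka[, 2L] < ph[, 1L], "deprotonate",
         ifelse(ph[, 2L] < pka[, 1L], "protonate", "both"))
}

as_interval <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
  } else {
    stopifnot(is.numeric(x), length(x) == 2L)
    x <- matrix(x, ncol = 2L)
  }
  if (any(x[, 1L] > x[, 2L])) stop("invalid interval: lo > hi", call. = FALSE)
  x
}

#' Target levels of a diprotic (phosphate/phosphonate) site
#'
#' A site with two ordered dissociation constants can exist fully protonated,
#' singly deprotonated, or doubly deprotonated. Each dissociation is judged
#' with the same interval-overlap rule as [decide_action()]: the fully
#' protonated form is kept while the first dissociation is not forced
#' (`protonate`/`both`), the doubly deprotonated form once the second
#' dissociation allows it (`deprotonate`/`both`), and the intermediate form
#' whenever the first proton can be lost while the second can be retained.
#' States that would deprotonate the second site before the first are never
#' produced.
#'
#' @param p1,p2 pKa intervals of the first and second dissociation
#'   (`c(lo, hi)` each).
#' @param ph pH interval `c(ph_min, ph_max)`.
#' @return non-empty character vector, a subset of `c("fully_protonated",
#'   "singly_deprotonated", "doubly_deprotonated")`.
#' @examples
#' diprotic_states(c(1.3, 3.1), c(6.5, 8.6), c(0, 14))  # all three forms
#' @export
diprotic_states <- function(p1, p2, ph) {
  a1 <- decide_action(p1, ph)
  a2 <- decide_action(p2, ph)
  states <- character(0)
  if (a1 %in% c("protonate", "both")) states <- c(states, "fully_protonated")
  if (a1 %in% c("deprotonate", "both") && a2 %in% c("protonate", "both")) {
    states <- c(states, "singly_deprotonated")
  }
  if (a2 %in% c("deprotonate", "both")) {
    states <- c(states, "doubly_deprotonated")
  }
  states
}

# States emitted for one decision unit (one monoprotic site, or one diprotic
# site carrying two pKa points) of a rule under a configuration.
unit_states <- function(rule_row, config) {
  ph <- c(config$ph_min, config$ph_max)
  n <- config$precision
  if (rule_row$class == "diprotic") {
    diprotic_states(pka_range(rule_row$mu1, rule_row$sigma1, n),
                    pka_range(rule_row$mu2, rule_row$sigma2, n), ph)
  } else {
    action <- decide_action(pka_range(rule_row$mu1, rule_row$sigma1, n), ph)
    switch(action,
           deprotonate = "deprotonated",
           protonate = "protonated",
           both = c("deprotonated", "protonated"))
  }
}

# Absolute formal-charge edits realizing one state of one site.
# `atoms`: ionizable atom index (length 1), or the two site atoms of a
# diprotic rule ordered by dissociation. Aromatic-nitrogen sites carry an
# explicit hydrogen count because implicit-valence rules cannot restore ring
# hydrogens.
state_edits <- function(rule_name, class, atoms, state) {
  arN <- rule_name %in% .aromatic_n_rules
  h_for <- function(has_h) if (arN) as.integer(has_h) else NULL
  if (class == "diprotic") {
    charges <- switch(state,
                      fully_protonated = c(0L, 0L),
                      singly_deprotonated = c(-1L, 0L),
                      doubly_deprotonated = c(-1L, -1L),
                      stop("unknown diprotic state: ", state, call. = FALSE))
    return(mapply(function(a, q) list(atom = a, charge = q, h = NULL),
                  atoms, charges, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  charge <- switch(paste(class, state),
                   "acid protonated" = 0L,
                   "acid deprotonated" = -1L,
                   "base protonated" = 1L,
                   "base deprotonated" = 0L,
                   stop("unknown state '", state, "' for class '", class, "'",
                        call. = FALSE))
  has_h <- (class == "acid" && state == "protonated") ||
    (class == "base" && state == "protonated")
  list(list(atom = atoms[1L], charge = charge, h = h_for(has_h)))
}

#' Set one ionizable site to an absolute protonation level
#'
#' Rewrites the ionizable atom's formal charge (and hydrogen count) to the
#' requested target level, regardless of how the input was drawn: deprotonated
#' acids get charge -1 and one fewer hydrogen, protonated basic nitrogens get
#' charge +1 and one more hydrogen. Applying a site's current level is a
#' no-op.
#'
#' @param smiles the molecule (a single SMILES; it is standardized first).
#' @param site one row of a [site_set][detect_sites] for a monoprotic site,
#'   or the two rows of a diprotic site.
#' @param level `"protonated"`/`"deprotonated"` for monoprotic sites;
#'   `"fully_protonated"`/`"singly_deprotonated"`/`"doubly_deprotonated"` for
#'   diprotic ones.
#' @return canonical SMILES of the edited molecule.
#' @examples
#' \dontrun{
#' s <- detect_sites("CC(=O)O")
#' set_site_state("CC(=O)O", s, "deprotonated")   # "CC(=O)[O-]"
#' }
#' @export
set_site_state <- function(smiles, site, level) {
  stopifnot(is.data.frame(site), nrow(site) %in% c(1L, 2L))
  mol <- parse_smiles(smiles, quiet = TRUE)
  atoms <- site$atom[order(site$site_no)]
  edits <- state_edits(site$rule[1L], site$class[1L], atoms, level)
  res <- backend_edit(list(list(smiles = mol, edits = edits)))[[1L]]
  if (!isTRUE(res$ok)) {
    stop("cannot set site (rule '", site$rule[1L], "', atom ", atoms[1L],
         ") to level '", level, "': ", res$error, call. = FALSE)
  }
  res$smiles
}

#' Enumerate the protomers of molecules over a pH range
#'
#' The full pipeline: each input is parsed and standardized, ionizable sites
#' are detected by prioritized SMARTS matching with masking
#' ([detect_sites()]), the interval-overlap rule selects the target state(s)
#' of every site ([decide_action()], [diprotic_states()]), and the Cartesian
#' product of per-site states is realized by absolute formal-charge edits.
#' Results are canonicalized, deduplicated, sorted lexicographically, and
#' truncated to `config$max_variants` per input. A molecule with no ionizable
#' sites yields exactly its standardized self; with `i` overlapping monoprotic
#' sites it yields `2^i` protomers (up to the cap).
#'
#' Unparseable records are skipped with a message (the batch continues);
#' combinations whose edit fails chemically are skipped individually.
#'
#' @param smiles character vector of input SMILES.
#' @param identifier optional character vector of identifiers, recycled
#'   against `smiles`; propagated to every protomer of the input.
#' @param rules a [rule_table][read_rule_table].
#' @param config a [protonation_config()].
#' @param quiet suppress skip/truncation messages.
#' @return a `protomer_set`: data.frame with columns `input`, `identifier`,
#'   `protomer` (canonical SMILES). The configuration is attached as
#'   attribute `config`, processing notes as attribute `log`.
#' @examples
#' \dontrun{
#' enumerate_protomers("Oc1ccccc1")                 # neutral + phenolate
#' enumerate_protomers("CCN(CC)CC(=O)Nc1c(C)cccc1C")  # lidocaine: 2 forms
#' }
#' @export
enumerate_protomers <- function(smiles, identifier = NULL,
                                rules = load_default_rules(),
                                config = protonation_config(),
                                quiet = FALSE) {
  stopifnot(is.character(smiles), inherits(config, "protonation_config"))
  if (is.null(identifier)) identifier <- rep("", length(smiles))
  identifier <- rep_len(as.character(identifier), length(smiles))
  log <- character(0)
  note <- function(msg) {
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }

  res <- backend_match(smiles, rules)
  # Per molecule: either a ready result (no sites / parse failure) or a list
  # of edit jobs indexed into one global batch.
  jobs <- list()
  plan <- vector("list", length(smiles))
  hard_cap <- max(config$max_variants, 4096L)
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) {
      note(paste0("skipping unparseable record ", i, " ('", smiles[i],
                  "'): ", r$error))
      plan[[i]] <- list(type = "skip")
      next
    }
    sites <- mask_sites(r$matches, rules, molecule = r$smiles)
    if (nrow(sites) == 0L) {
      plan[[i]] <- list(type = "self", smiles = r$smiles)
      next
    }
    # decision units: one per (rule, match); diprotic units span two rows
    key <- paste(sites$rule, sites$match_id)
    units <- lapply(split(seq_len(nrow(sites)), key), function(idx) {
      rows <- sites[idx, , drop = FALSE]
      rule_row <- rules[match(rows$rule[1L], rules$name), , drop = FALSE]
      list(atoms = rows$atom[order(rows$site_no)],
           rule = rows$rule[1L], class = rows$class[1L],
           states = unit_states(rule_row, config))
    })
    grid <- expand.grid(lapply(units, function(u) seq_along(u$states)),
                        KEEP.OUT.ATTRS = FALSE)
    if (nrow(grid) > hard_cap) {
      note(paste0("record ", i, ": ", nrow(grid),
                  " state combinations; enumerating the first ", hard_cap))
      grid <- grid[seq_len(hard_cap), , drop = FALSE]
    }
    job_idx <- integer(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      edits <- list()
      for (u in seq_along(units)) {
        unit <- units[[u]]
        edits <- c(edits, state_edits(unit$rule, unit$class, unit$atoms,
                                      unit$states[[grid[g, u]]]))
      }
      jobs[[length(jobs) + 1L]] <- list(smiles = r$smiles, edits = edits)
      job_idx[g] <- length(jobs)
    }
    plan[[i]] <- list(type = "enumerate", jobs = job_idx)
  }

  edited <- backend_edit(jobs)
  rows <- vector("list", length(smiles))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    if (p$type == "skip") next
    if (p$type == "self") {
      out <- p$smiles
    } else {
      out <- character(0)
      for (j in p$jobs) {
        e <- edited[[j]]
        if (isTRUE(e$ok)) {
          out <- c(out, e$smiles)
        } else {
          note(paste0("record ", i, ": skipping one state combination (",
                      e$error, ")"))
        }
      }
      out <- sort(unique(out), method = "radix")
      if (length(out) > config$max_variants) {
        note(paste0("record ", i, ": ", length(out),
                    " protomers, truncating to ", config$max_variants))
        out <- out[seq_len(config$max_variants)]
      }
      if (length(out) == 0L) {
        note(paste0("record ", i, ": all state combinations failed; ",
                    "emitting the standardized input"))
        out <- res[[i]]$smiles
      }
    }
    rows[[i]] <- data.frame(input = smiles[i], identifier = identifier[i],
                            protomer = out, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(0), identifier = character(0),
               protomer = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "log") <- log
  class(out) <- c("protomer_set", "data.frame")
  out
}

#' @export
print.protomer_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Protomer set: ", nrow(x), " protomer(s) from ",
      length(unique(x$input)), " input(s)", sep = "")
  if (!is.null(cfg)) {
    cat(sprintf(" [pH %.2f-%.2f, n = %.2f]", cfg$ph_min, cfg$ph_max,
                cfg$precision))
  }
  cat("\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Henderson-Hasselbalch ionization fraction
#'
#' Population fraction of the deprotonated (or protonated) form of a
#' monoprotic site with acid dissociation constant `pka` at a given `ph`:
#' `deprotonated = 1 / (1 + 10^(pka - ph))`.
#'
#' @param pka pKa value(s).
#' @param ph pH value(s).
#' @param form which form's fraction to return.
#' @return numeric fraction(s) in (0, 1).
#' @examples
#' hh_fraction(4.0, 7.4)                  # 0.9996...
#' hh_fraction(7.3, 7.4, "protonated")    # 0.4427...
#' @export
hh_fraction <- function(pka, ph, form = c("deprotonated", "protonated")) {
  form <- match.arg(form)
  stopifnot(is.numeric(pka), is.numeric(ph), all(is.finite(pka)),
            all(is.finite(ph)))
  deprot <- 1 / (1 + 10^(pka - ph))
  if (form == "deprotonated") deprot else 1 - deprot
}
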