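#' Curate a raw labeled pKa dataset
#'
#' Applies the curation filters used when assembling a moiety-labeled pKa
#' benchmark from heterogeneous sources:
#' \itemize{
#'   \item multi-fragment SMILES (salts) are discarded;
#'   \item replicate pKa measurements for a site (`;`-separated in `pka1` /
#'     `pka2`) spanning more than 1.0 pKa unit are treated as experimental
#'     uncertainty and the record is discarded, otherwise replicates are
#'     averaged;
#'   \item records with pKa outside `[-1.74, 15.7]` (hydronium to water) are
#'     discarded unless their moiety is on the exception list;
#'   \item nitro-labeled records are kept and assigned the sentinel
#'     pseudo-pKa -1000 so nitro oxygens are always deprotonated.
#' }
#'
#' @param records data.frame with columns `smiles`, `pka1`, optionally
#'   `pka2` (diprotic second dissociation), and `moiety`. `pka1`/`pka2` may be
#'   numeric or character with `;`-separated replicate values.
#' @param exceptions moieties exempt from the pKa bounds (default: the
#'   sulfonate/sulfate groups measured below -1.74 and the alcohol, amide and
#'   protonated-aromatic-nitrogen groups measured above 15.7).
#' @param bounds numeric `c(lo, hi)` retention bounds.
#' @return data.frame of retained `LabeledCompound` rows (`smiles`, `pka1`,
#'   `pka2`, `moiety`), with the discarded records and their reasons attached
#'   as attribute `rejections` (a data.frame with columns `smiles`,
#'   `reason`).
#' @export
curate <- function(records,
                   exceptions = c("sulfonate", "sulfate", "alcohol", "amide",
                                  "aromatic_n_protonated"),
                   bounds = c(-1.74, 15.7)) {
  stopifnot(is.data.frame(records),
            all(c("smiles", "pka1", "moiety") %in% names(records)))
  if (!"pka2" %in% names(records)) records$pka2 <- NA
  reject <- data.frame(smiles = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  keep <- logical(nrow(records))
  pka1 <- numeric(nrow(records))
  pka2 <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    smi <- records$smiles[i]
    if (grepl(".", smi, fixed = TRUE)) {
      reject <- rbind(reject, data.frame(smiles = smi,
                                         reason = "multi-fragment (salt)"))
      next
    }
    v1 <- replicate_values(records$pka1[i])
    v2 <- replicate_values(records$pka2[i])
    if (length(v1) == 0L) {
      reject <- rbind(reject, data.frame(smiles = smi,
                                         reason = "no pKa value"))
      next
    }
    if (diff(range(v1)) > 1.0 ||
        (length(v2) > 0L && diff(range(v2)) > 1.0)) {
      reject <- rbind(reject, data.frame(smiles = smi,
                                         reason = "replicate span > 1.0"))
      next
    }
    p1 <- mean(v1)
    p2 <- if (length(v2) > 0L) mean(v2) else NA_real_
    moiety <- records$moiety[i]
    if (identical(moiety, "nitro")) {
      p1 <- -1000.0
    } else if (!moiety %in% exceptions) {
      vals <- c(p1, p2)
      vals <- vals[!is.na(vals)]
      if (any(vals < bounds[1L] | vals > bounds[2L])) {
        reject <- rbind(reject, data.frame(
          smiles = smi,
          reason = paste0("pKa outside [", bounds[1L], ", ", bounds[2L], "]")))
        next
      }
    }
    keep[i] <- TRUE
    pka1[i] <- p1
    pka2[i] <- p2
  }
  out <- data.frame(smiles = records$smiles[keep], pka1 = pka1[keep],
                    pka2 = pka2[keep], moiety = records$moiety[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejections") <- reject
  out
}

replicate_values <- function(x) {
  if (length(x) == 0L || is.na(x)) return(numeric(0))
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(strsplit(as.character(x), ";",
                                            fixed = TRUE)[[1L]]))
  v[!is.na(v)]
}

# Required state set of a compound given its experimental pKa value(s) and a
# pH window: the degenerate interval [pKa, pKa] pushed through the same
# decision rules the engine uses (boundary pKa values therefore require both
# states).
required_states <- function(pka1, pka2, config) {
  ph <- c(config$ph_min, config$ph_max)
  if (is.na(pka2)) {
    switch(decide_action(c(pka1, pka1), ph),
           deprotonate = "deprotonated",
           protonate = "protonated",
           both = c("deprotonated", "protonated"))
  } else {
    diprotic_states(c(pka1, pka1), c(pka2, pka2), ph)
  }
}

#' Classify one prediction as correct, excess, or incorrect
#'
#' Compares the state set emitted by the engine for a compound's labeled site
#' with the set required by its experimental pKa over the pH window:
#' `correct` when the sets are equal, `excess` when the emitted set strictly
#' contains the required set (extra states needlessly enlarge the library),
#' and `incorrect` when any required state is missing (a relevant state is
#' never generated). For diprotic compounds the required set is built from
#' both dissociation constants over the three ordered levels.
#'
#' @param pka experimental pKa value, or `c(pKa1, pKa2)` for a diprotic
#'   compound.
#' @param emitted character vector of emitted states (monoprotic: among
#'   `"deprotonated"`, `"protonated"`; diprotic: among the three level
#'   names).
#' @param config a [protonation_config()] (only the pH window is used).
#' @return `"correct"`, `"excess"`, or `"incorrect"`.
#' @examples
#' cfg <- protonation_config()
#' classify_outcome(4.0, "deprotonated", cfg)                    # correct
#' classify_outcome(4.0, c("deprotonated", "protonated"), cfg)   # excess
#' classify_outcome(7.0, "deprotonated", cfg)                    # incorrect
#' @export
classify_outcome <- function(pka, emitted, config = protonation_config()) {
  stopifnot(is.numeric(pka), length(pka) %in% c(1L, 2L))
  if (length(emitted) == 0L) {
    stop("emitted state set is empty", call. = FALSE)
  }
  required <- required_states(pka[1L], if (length(pka) == 2L) pka[2L] else NA,
                              config)
  if (setequal(emitted, required)) return("correct")
  if (all(required %in% emitted)) return("excess")
  "incorrect"
}

# Engine-detected site rule per dataset row (one backend call). Returns a
# character vector: the rule name whose detected site matches the labeled
# moiety, or NA with a log message when the moiety is not detected.
dataset_site_rules <- function(dataset, rules, quiet = FALSE) {
  sets <- detect_sites(dataset$smiles, rules, quiet = quiet)
  if (nrow(dataset) == 1L) sets <- list(sets)
  vapply(seq_len(nrow(dataset)), function(i) {
    s <- sets[[i]]
    if (is.null(s)) return(NA_character_)
    if (dataset$moiety[i] %in% s$rule) dataset$moiety[i] else NA_character_
  }, character(1))
}

tally_outcomes <- function(outcomes) {
  n <- length(outcomes)
  counts <- vapply(c("correct", "excess", "incorrect"),
                   function(o) sum(outcomes == o), integer(1))
  structure(list(n_total = n, counts = counts,
                 percent = if (n > 0) 100 * counts / n else counts * NA_real_),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat("Outcome tally over ", x$n_total, " compounds:\n", sep = "")
  for (o in names(x$counts)) {
    cat(sprintf("  %-9s %5d  (%.1f%%)\n", o, x$counts[[o]], x$percent[[o]]))
  }
  invisible(x)
}

#' Tally correct/excess/incorrect outcomes over a labeled dataset
#'
#' Runs the engine's state selection for every compound's labeled site (the
#' site is located with [detect_sites()]; compounds whose labeled moiety is
#' not detected are logged as dataset errors and excluded) and classifies the
#' emitted state set against the experimental pKa with [classify_outcome()].
#'
#' @param dataset data.frame with columns `smiles`, `pka1`, optional `pka2`,
#'   `moiety` (as produced by [curate()] or [make_moiety_compounds()]).
#' @param rules a [rule_table][read_rule_table].
#' @param config a [protonation_config()].
#' @param site_rules optional precomputed result of the internal site
#'   detection (used by [sweep_precision()] to avoid re-matching).
#' @param quiet suppress messages.
#' @return an `outcome_tally`: list with `n_total`, `counts`, `percent`.
#' @export
tally <- function(dataset, rules = load_default_rules(),
                  config = protonation_config(), site_rules = NULL,
                  quiet = FALSE) {
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0L)
  if (!"pka2" %in% names(dataset)) dataset$pka2 <- NA_real_
  if (is.null(site_rules)) {
    site_rules <- dataset_site_rules(dataset, rules, quiet = quiet)
  }
  usable <- !is.na(site_rules)
  if (any(!usable) && !quiet) {
    message(sum(!usable), " compound(s) excluded: labeled moiety not ",
            "detected by the engine")
  }
  outcomes <- vapply(which(usable), function(i) {
    rule_row <- rules[match(site_rules[i], rules$name), , drop = FALSE]
    emitted <- unit_states(rule_row, config)
    pka <- dataset$pka1[i]
    if (!is.na(dataset$pka2[i])) pka <- c(pka, dataset$pka2[i])
    classify_outcome(pka, emitted, config)
  }, character(1))
  tally_outcomes(outcomes)
}

#' Sweep the pKa precision factor over a labeled dataset
#'
#' Recomputes the outcome tally for each precision factor `n`; as `n` grows
#' every pKa interval widens, so excess percentages are non-decreasing and
#' incorrect percentages non-increasing.
#'
#' @inheritParams tally
#' @param n_values numeric vector of precision factors.
#' @return data.frame with one row per `n`: columns `n`, `n_total`,
#'   `correct`, `excess`, `incorrect` (percentages).
#' @export
sweep_precision <- function(dataset, rules = load_default_rules(),
                            config = protonation_config(),
                            n_values = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                            quiet = FALSE) {
  site_rules <- dataset_site_rules(dataset, rules, quiet = quiet)
  rows <- lapply(n_values, function(n) {
    cfg <- protonation_config(config$ph_min, config$ph_max, n,
                              config$max_variants)
    t <- tally(dataset, rules, cfg, site_rules = site_rules, quiet = TRUE)
    data.frame(n = n, n_total = t$n_total,
               correct = t$percent[["correct"]],
               excess = t$percent[["excess"]],
               incorrect = t$percent[["incorrect"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-moiety threefold cross-validation of the pKa-range model
#'
#' For each moiety with at least `k` compounds: compounds are shuffled with
#' an explicit seed and split into `k` folds by index modulo `k`. For every
#' fold, the pKa mean and standard deviation are estimated from the training
#' two-thirds, the resulting interval (at the configuration's precision
#' factor) drives the state decision, and the held-out third is classified
#' against its experimental values. Reported are the mean and standard
#' deviation over folds of the correct/excess/incorrect percentages.
#'
#' @inheritParams tally
#' @param k number of folds (default 3).
#' @param seed integer seed for the fold shuffle (recorded in the output).
#' @return data.frame with one row per evaluated moiety: `moiety`, `n`,
#'   `correct_mean`, `correct_sd`, `excess_mean`, `excess_sd`,
#'   `incorrect_mean`, `incorrect_sd`. Moieties with fewer than `k` compounds
#'   are skipped with a warning. The seed is attached as attribute `seed`.
#' @export
crossvalidate_moiety <- function(dataset, config = protonation_config(),
                                 k = 3L, seed = 1L, quiet = FALSE) {
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0L, k >= 2L)
  if (!"pka2" %in% names(dataset)) dataset$pka2 <- NA_real_
  rows <- list()
  for (moiety in unique(dataset$moiety)) {
    sub <- dataset[dataset$moiety == moiety, , drop = FALSE]
    if (nrow(sub) < k) {
      warning("moiety '", moiety, "' has fewer than ", k,
              " compounds; skipped", call. = FALSE)
      next
    }
    perm <- with_seed(seed, sample.int(nrow(sub)))
    fold <- (seq_along(perm) - 1L) %% k + 1L
    pct <- matrix(NA_real_, nrow = k, ncol = 3,
                  dimnames = list(NULL, c("correct", "excess", "incorrect")))
    for (f in seq_len(k)) {
      test_idx <- perm[fold == f]
      train_idx <- perm[fold != f]
      train <- sub[train_idx, , drop = FALSE]
      test <- sub[test_idx, , drop = FALSE]
      diprotic <- !all(is.na(sub$pka2))
      mu1 <- mean(train$pka1); s1 <- stats::sd(train$pka1)
      if (length(train_idx) < 2L || is.na(s1)) s1 <- 0
      ph <- c(config$ph_min, config$ph_max)
      n <- config$precision
      if (diprotic) {
        mu2 <- mean(train$pka2, na.rm = TRUE)
        s2 <- stats::sd(train$pka2)
        if (is.na(s2)) s2 <- 0
        emitted <- diprotic_states(pka_range(mu1, s1, n),
                                   pka_range(mu2, s2, n), ph)
      } else {
        emitted <- switch(decide_action(pka_range(mu1, s1, n), ph),
                          deprotonate = "deprotonated",
                          protonate = "protonated",
                          both = c("deprotonated", "protonated"))
      }
      outcomes <- vapply(seq_len(nrow(test)), function(i) {
        pka <- test$pka1[i]
        if (!is.na(test$pka2[i])) pka <- c(pka, test$pka2[i])
        classify_outcome(pka, emitted, config)
      }, character(1))
      t <- tally_outcomes(outcomes)
      pct[f, ] <- t$percent
    }
    rows[[length(rows) + 1L]] <- data.frame(
      moiety = moiety, n = nrow(sub),
      correct_mean = mean(pct[, "correct"]),
      correct_sd = stats::sd(pct[, "correct"]),
      excess_mean = mean(pct[, "excess"]),
      excess_sd = stats::sd(pct[, "excess"]),
      incorrect_mean = mean(pct[, "incorrect"]),
      incorrect_sd = stats::sd(pct[, "incorrect"]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(moiety = character(0))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched (seeds are explicit arguments, never global state).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Read / write a labeled pKa dataset
#'
#' Comma- or tab-separated with header `smiles,pka1[,pka2],moiety`
#' (delimiter inferred from the header line). `pka1`/`pka2` may carry
#' `;`-separated replicate values (see [curate()]).
#'
#' @param path file path.
#' @return data.frame with columns `smiles`, `pka1`, `pka2` (optional),
#'   `moiety`.
#' @export
read_pka_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("smiles", "pka1", "moiety"), names(df))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_pka_dataset
#' @param dataset data.frame to write.
#' @param sep field separator (default `","`).
#' @export
write_pka_dataset <- function(dataset, path, sep = ",") {
  utils::write.table(dataset, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
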