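#' Parse and standardize SMILES
#'
#' Parses each SMILES and standardizes it so that substructure matching sees
#' one canonical input form: aromaticity is perceived (aromatic and Kekule
#' spellings converge), the written variants of azides collapse to the
#' charge-separated `N=[N+]=[N-]` form, uncharged nitro `N(=O)=O` is rewritten
#' to `[N+](=O)[O-]`, and for multi-fragment (dot-separated) inputs only the
#' largest fragment is kept (with a message). Stereochemistry present in the
#' input is preserved.
#'
#' @param smiles character vector of SMILES strings.
#' @param on_error `"stop"` (default) raises on the first unparseable SMILES;
#'   `"na"` returns `NA` for failed records and reports them via a message.
#' @param quiet suppress messages about dropped fragments/records.
#' @return character vector of standardized canonical SMILES, same length as
#'   the input (with `NA` for failures when `on_error = "na"`).
#' @examples
#' \dontrun{
#' parse_smiles(c("Oc1ccccc1", "OC1=CC=CC=C1"))  # identical canonical forms
#' parse_smiles("NN#N")                          # "[N-]=[N+]=N"
#' }
#' @export
parse_smiles <- function(smiles, on_error = c("stop", "na"), quiet = FALSE) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  smiles <- trimws(smiles)
  if (any(!nzchar(smiles) | is.na(smiles))) {
    stop("empty SMILES string", call. = FALSE)
  }
  res <- backend_parse(smiles)
  out <- vapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (isTRUE(r$ok)) {
      if (isTRUE(r$fragment_dropped) && !quiet) {
        message("multi-fragment input; kept largest fragment: ", smiles[i])
      }
      r$smiles
    } else {
      if (on_error == "stop") {
        stop("SMILES parse error: ", r$error, call. = FALSE)
      }
      if (!quiet) message("skipping unparseable SMILES: ", smiles[i])
      NA_character_
    }
  }, character(1))
  out
}

#' Standardize ionizable group notation
#'
#' Collapses the written variants of azides (`N[N+]#N`, `N=[N+]=N`, `NN#N`,
#' `N=N=N`) to the charge-separated form and rewrites uncharged nitro
#' `N(=O)=O` to `[N+](=O)[O-]`, so SMARTS matching sees one notation per
#' group. Molecules without such groups pass through unchanged (up to
#' canonicalization). This step is idempotent and is also applied by
#' [parse_smiles()]; it is exposed separately for clarity in pipelines.
#'
#' @inheritParams parse_smiles
#' @return character vector of standardized canonical SMILES.
#' @export
standardize_groups <- function(smiles, quiet = TRUE) {
  parse_smiles(smiles, on_error = "stop", quiet = quiet)
}

#' Canonical SMILES of already-standardized molecules
#'
#' Equivalent to [parse_smiles()]; provided so that deduplication code reads
#' naturally. Two inputs describing the same molecule yield the same string.
#'
#' @inheritParams parse_smiles
#' @return character vector of canonical SMILES.
#' @export
to_canonical_smiles <- function(smiles, quiet = TRUE) {
  parse_smiles(smiles, on_error = "stop", quiet = quiet)
}

#' Read a SMILES library file
#'
#' One molecule per line: the first whitespace-separated token is the SMILES,
#' the remainder (if any) an identifier. Blank lines and lines starting with
#' `#` are ignored. Lines whose SMILES fails to parse are skipped, counted,
#' and reported via a message; parsing/standardization is *not* applied to
#' the returned SMILES (see [parse_smiles()]), only used for screening.
#'
#' @param path path to a SMILES file.
#' @param validate screen each record through the parser and drop unparseable
#'   ones (default `TRUE`).
#' @param quiet suppress the skipped-record message.
#' @return data.frame with columns `smiles`, `identifier`; the number of
#'   skipped lines is attached as attribute `n_skipped`.
#' @export
read_smiles_file <- function(path, validate = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  smiles <- sub("\\s.*$", "", lines)
  identifier <- trimws(sub("^\\S+", "", lines))
  n_skipped <- 0L
  if (validate && length(smiles) > 0L) {
    parsed <- parse_smiles(smiles, on_error = "na", quiet = TRUE)
    keep <- !is.na(parsed)
    n_skipped <- sum(!keep)
    if (n_skipped > 0L && !quiet) {
      message("skipped ", n_skipped, " unparseable record(s) in ", path)
    }
    smiles <- smiles[keep]
    identifier <- identifier[keep]
  }
  out <- data.frame(smiles = smiles, identifier = identifier,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a SMILES library file
#'
#' Writes `SMILES<TAB>identifier` lines (the identifier column is omitted for
#' records with an empty identifier), the dialect read by
#' [read_smiles_file()].
#'
#' @param records data.frame with columns `smiles` and optionally
#'   `identifier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(records, path) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records))
  id <- if ("identifier" %in% names(records)) records$identifier else ""
  id <- ifelse(is.na(id), "", id)
  lines <- ifelse(nzchar(id), paste(records$smiles, id, sep = "\t"),
                  records$smiles)
  writeLines(lines, path)
  invisible(path)
}
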