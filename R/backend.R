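#' @title RDKit chemistry backend
#'
#' @description
#' All molecule-level primitives (SMILES parsing, standardization, SMARTS
#' matching with atom indices, formal-charge edits, canonicalization) are
#' performed by RDKit through a bundled Python helper script, invoked once per
#' *batch* of molecules with a JSON request/response exchanged over temporary
#' files. Protonation decisions never happen in the helper; it is a pure
#' structure service.
#'
#' The Python interpreter is located from `options(ionstate.python = ...)`,
#' then the `IONSTATE_PYTHON` environment variable, then `python` on the PATH.
#' @name ionstate-backend
#' @keywords internal
NULL

backend_python <- function() {
  py <- getOption("ionstate.python", "")
  if (!nzchar(py)) py <- Sys.getenv("IONSTATE_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("no Python interpreter found; set options(ionstate.python = ...)",
         call. = FALSE)
  }
  py
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "ionstate")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled chemistry helper 'python/chem_backend.py' not found; ",
         "the ionstate installation is corrupt", call. = FALSE)
  }
  path
}

#' Issue one batched request to the chemistry helper
#'
#' @param request named list, serialized to JSON (`op` plus op-specific
#'   fields).
#' @return parsed JSON response (lists, not simplified).
#' @keywords internal
backend_call <- function(request) {
  req_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(req_file, out_file)), add = TRUE)
  jsonlite::write_json(request, req_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(backend_python(), c(backend_script(), req_file, out_file),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(out_file)) {
    stop("chemistry backend failed (exit status ", status, ")", call. = FALSE)
  }
  resp <- jsonlite::read_json(out_file, simplifyVector = FALSE)
  if (!is.null(resp$error)) stop("chemistry backend: ", resp$error, call. = FALSE)
  resp
}

#' Standardize a batch of SMILES and match a set of SMARTS patterns
#'
#' @param smiles character vector.
#' @param patterns data.frame with columns `name`, `smarts` (may have zero
#'   rows, in which case only standardization is performed).
#' @return list with one element per input: either
#'   `list(ok = FALSE, error = ...)` or `list(ok = TRUE, smiles = <canonical>,
#'   fragment_dropped = <flag>, n_heavy = <count>, matches = <named list of
#'   integer matrices, one row per match, 1-based atom indices>)`.
#' @keywords internal
backend_match <- function(smiles, patterns) {
  pat <- lapply(seq_len(nrow(patterns)), function(i) {
    list(name = patterns$name[[i]], smarts = patterns$smarts[[i]])
  })
  resp <- backend_call(list(op = "match", smiles = as.list(smiles),
                            patterns = pat))
  lapply(resp$results, function(r) {
    if (isTRUE(r$ok)) {
      r$matches <- lapply(r$matches, function(ms) {
        do.call(rbind, lapply(ms, function(m) as.integer(unlist(m)) + 1L))
      })
    }
    r
  })
}

#' Apply absolute formal-charge/hydrogen edits to molecules
#'
#' @param jobs list of `list(smiles =, edits = list(list(atom = <1-based>,
#'   charge =, h = <int or NULL>)))`.
#' @return list of `list(ok, smiles | error)` per job.
#' @keywords internal
backend_edit <- function(jobs) {
  if (length(jobs) == 0L) return(list())
  jobs0 <- lapply(jobs, function(j) {
    j$edits <- lapply(j$edits, function(e) {
      e$atom <- as.integer(e$atom) - 1L
      e
    })
    j
  })
  backend_call(list(op = "edit", jobs = jobs0))$results
}

#' Parse/standardize a batch of SMILES without matching
#' @keywords internal
backend_parse <- function(smiles) {
  backend_call(list(op = "parse", smiles = as.list(smiles)))$results
}
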