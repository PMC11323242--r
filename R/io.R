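# Plain-SMILES and evaluation-log CSV input/output.

LOG_COLUMNS <- c("call_index", "elapsed_seconds", "canonical_smiles",
                 "raw_oracle", "property_pass", "df_pass", "final_score")

#' Read a SMILES file
#'
#' Line-oriented: the first whitespace-separated token of each line is the
#' SMILES, an optional second token is the molecule name. Blank lines are
#' skipped. Unparsable lines yield records with `valid = FALSE` rather than
#' errors.
#'
#' @param path Path to the file.
#' @param config A [fingerprint_config()].
#' @return A list of `molecule_record`s; names are taken from the second
#'   token where present.
#' @export
read_smiles_file <- function(path, config = fingerprint_config()) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0L) return(list())
  tok <- strsplit(trimws(ln), "\\s+")
  smi <- vapply(tok, `[[`, "", 1L)
  nm <- vapply(tok, function(t) if (length(t) >= 2L) t[[2L]] else "", "")
  recs <- parse_molecules(smi, config)
  if (any(nzchar(nm))) names(recs) <- nm
  recs
}

#' Write a SMILES file
#'
#' @param records List of `molecule_record`s (invalid ones are skipped with a
#'   warning) or a `screening_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(records, path) {
  if (inherits(records, "screening_library")) records <- records$records
  valid <- vapply(records, function(r) isTRUE(r$valid), TRUE)
  if (any(!valid))
    warning(sum(!valid), " invalid record(s) skipped when writing ", path)
  recs <- records[valid]
  smi <- vapply(recs, `[[`, "", "canonical_smiles")
  nm <- names(recs)
  out <- if (is.null(nm)) smi else {
    ifelse(nzchar(nm), paste(smi, nm, sep = "\t"), smi)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an evaluation log as CSV
#'
#' Columns: `call_index, elapsed_seconds, canonical_smiles, raw_oracle,
#' property_pass, df_pass, final_score`. Numeric fields are serialized with
#' 17 significant digits so [read_log_csv()] round-trips every double
#' bit-exactly, and identical logs always serialize to identical bytes.
#'
#' @param log A data frame with the columns above (e.g. `result$log` from
#'   [run_generator()]), or a `run_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(log, path) {
  log <- as_evaluation_log(log)
  df <- data.frame(
    call_index = sprintf("%d", log$call_index),
    elapsed_seconds = sprintf("%.17g", log$elapsed_seconds),
    canonical_smiles = log$canonical_smiles,
    raw_oracle = sprintf("%.17g", log$raw_oracle),
    property_pass = ifelse(log$property_pass, "TRUE", "FALSE"),
    df_pass = ifelse(log$df_pass, "TRUE", "FALSE"),
    final_score = sprintf("%.17g", log$final_score),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read an evaluation log CSV
#'
#' @param path Path written by [write_log_csv()].
#' @return A data frame with the canonical log columns and types.
#' @export
read_log_csv <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = ",", header = TRUE, quote = "",
                      stringsAsFactors = FALSE,
                      colClasses = c("integer", "numeric", "character",
                                     "numeric", "logical", "logical",
                                     "numeric")),
    error = function(e) stop("malformed log CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(df), LOG_COLUMNS))
    stop("malformed log CSV ", path, ": header must be ",
         paste(LOG_COLUMNS, collapse = ","))
  df$canonical_smiles[is.na(df$canonical_smiles)] <- ""
  df
}

as_evaluation_log <- function(x) {
  if (inherits(x, "run_result")) x <- x$log
  stopifnot(is.data.frame(x))
  missing <- setdiff(LOG_COLUMNS, names(x))
  if (length(missing) > 0L)
    stop("log is missing column(s): ", paste(missing, collapse = ", "))
  x[LOG_COLUMNS]
}
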