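# The composite scoring function: pluggable bioactivity oracle x binary
# property filters x diversity filter, with hit determination.
#
# The final score of a molecule is the product of the oracle's probabilistic
# activity output in [0,1] and two binary filters: a property filter (lenient
# medicinal-chemistry ranges for MW, logP and the fraction of idiosyncratic
# substructures) and a diversity filter that zeroes molecules too close to
# previously found hits, forcing generators to explore new regions.

#' Property filter configuration
#'
#' Lenient acceptability ranges; molecules violating any range have their
#' score set to zero. Defaults: MW in \[157, 761\] Da, logP in \[-2.0, 8.3\],
#' idiosyncratic-substructure fraction in \[0.00, 0.08\].
#'
#' @param mw_range Closed interval, Daltons.
#' @param logp_range Closed interval.
#' @param idio_range Closed interval for the idiosyncratic fraction.
#' @param reference_vocabulary Numeric vector of circular substructure keys
#'   considered "known" (see [vocabulary_from_records()]). If `NULL`, the
#'   idiosyncrasy criterion is not assessed and only MW/logP are checked.
#' @return An object of class `property_filter_config`.
#' @export
property_filter_config <- function(mw_range = c(157, 761),
                                   logp_range = c(-2.0, 8.3),
                                   idio_range = c(0.00, 0.08),
                                   reference_vocabulary = NULL) {
  stopifnot(length(mw_range) == 2L, mw_range[1] <= mw_range[2],
            length(logp_range) == 2L, logp_range[1] <= logp_range[2],
            length(idio_range) == 2L, idio_range[1] <= idio_range[2])
  structure(list(mw_range = as.numeric(mw_range),
                 logp_range = as.numeric(logp_range),
                 idio_range = as.numeric(idio_range),
                 reference_vocabulary = reference_vocabulary),
            class = "property_filter_config")
}

#' Fraction of idiosyncratic substructures
#'
#' The fraction of a molecule's atom-centered circular substructure keys
#' (radii 0..radius of its fingerprint configuration) that are absent from a
#' reference vocabulary. Molecules assembled from substructures common in a
#' reference collection score near 0; exotic ones approach 1.
#'
#' @param record A valid `molecule_record`.
#' @param reference_vocabulary Nonempty numeric vector of keys, e.g. from
#'   [vocabulary_from_records()].
#' @return Fraction in \[0, 1\]; a molecule with no keys returns 0.
#' @export
idiosyncratic_fraction <- function(record, reference_vocabulary) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid))
  if (is.null(reference_vocabulary) || length(reference_vocabulary) == 0L)
    stop("reference_vocabulary must be a nonempty set of substructure keys")
  keys <- record$substructure_keys
  if (length(keys) == 0L) return(0)
  mean(!(keys %in% reference_vocabulary))
}

#' Build a substructure-key vocabulary from a reference collection
#'
#' @param records List of `molecule_record`s or a `screening_library`.
#' @return Sorted numeric vector of all circular keys observed in the valid
#'   records.
#' @export
vocabulary_from_records <- function(records) {
  if (inherits(records, "screening_library")) records <- records$records
  keys <- unlist(lapply(records, function(r)
    if (isTRUE(r$valid)) r$substructure_keys else NULL))
  sort(unique(keys))
}

#' Binary property filter
#'
#' @param record A `molecule_record`; invalid records fail the filter.
#' @param cfg A [property_filter_config()].
#' @return `TRUE` iff MW, logP and (when a vocabulary is configured) the
#'   idiosyncratic fraction all lie inside their closed ranges.
#' @export
property_filter <- function(record, cfg = property_filter_config()) {
  stopifnot(inherits(record, "molecule_record"),
            inherits(cfg, "property_filter_config"))
  if (!isTRUE(record$valid)) return(FALSE)
  if (record$mw < cfg$mw_range[1] || record$mw > cfg$mw_range[2]) return(FALSE)
  if (record$logp < cfg$logp_range[1] || record$logp > cfg$logp_range[2]) return(FALSE)
  if (!is.null(cfg$reference_vocabulary)) {
    f <- idiosyncratic_fraction(record, cfg$reference_vocabulary)
    if (f < cfg$idio_range[1] || f > cfg$idio_range[2]) return(FALSE)
  }
  TRUE
}

# ---- diversity filter -------------------------------------------------------

#' Diversity filter memory
#'
#' A scoring-time memory of previously found hits. A candidate within
#' `distance_threshold` (Tanimoto distance) of any stored hit gets its score
#' zeroed, steering the generator away from already-discovered regions. The
#' memory is monotone: fingerprints are only appended, never removed.
#'
#' @param distance_threshold Distance threshold D_DF; default 0.7.
#' @param hit_score_threshold Raw-score threshold S above which passing
#'   molecules are memorized; default 0.5.
#' @return An object of class `diversity_filter` (environment-backed, so it
#'   is updated in place by [df_register_hit()]).
#' @export
diversity_filter <- function(distance_threshold = 0.7,
                             hit_score_threshold = 0.5) {
  stopifnot(distance_threshold >= 0, distance_threshold <= 1,
            hit_score_threshold > 0, hit_score_threshold < 1)
  e <- new.env(parent = emptyenv())
  e$fps <- list()
  e$distance_threshold <- distance_threshold
  e$hit_score_threshold <- hit_score_threshold
  class(e) <- "diversity_filter"
  e
}

#' @export
print.diversity_filter <- function(x, ...) {
  cat(sprintf("<diversity filter> %d stored hit(s), D_DF = %g, S = %g\n",
              length(x$fps), x$distance_threshold, x$hit_score_threshold))
  invisible(x)
}

#' Diversity-filter check
#'
#' @param state A [diversity_filter()].
#' @param fp A fingerprint (on-bit index vector).
#' @return `TRUE` iff the distance to every stored hit fingerprint exceeds
#'   the threshold (an empty memory passes everything).
#' @export
df_check <- function(state, fp) {
  stopifnot(inherits(state, "diversity_filter"))
  thr <- state$distance_threshold
  for (h in state$fps) if (tanimoto_distance(fp, h) <= thr) return(FALSE)
  TRUE
}

#' Register a hit in the diversity-filter memory
#'
#' @inheritParams df_check
#' @return The filter, invisibly (it is modified in place).
#' @export
df_register_hit <- function(state, fp) {
  stopifnot(inherits(state, "diversity_filter"))
  state$fps[[length(state$fps) + 1L]] <- fp
  invisible(state)
}

# ---- composite score --------------------------------------------------------

#' Bundle an oracle, filters, diversity filter and hit threshold
#'
#' @param oracle A function mapping a valid `molecule_record` to a score in
#'   \[0, 1\] (the probabilistic bioactivity output).
#' @param filters A [property_filter_config()].
#' @param df A [diversity_filter()], or `NULL` to disable the filter.
#' @param S Hit threshold in (0, 1); default 0.5.
#' @param fp_config The [fingerprint_config()] used to parse proposals.
#' @return An object of class `scoring_context`.
#' @export
scoring_context <- function(oracle, filters = property_filter_config(),
                            df = diversity_filter(), S = 0.5,
                            fp_config = fingerprint_config()) {
  stopifnot(is.function(oracle), inherits(filters, "property_filter_config"),
            is.null(df) || inherits(df, "diversity_filter"),
            S > 0, S < 1, inherits(fp_config, "fingerprint_config"))
  structure(list(oracle = oracle, filters = filters, df = df, S = S,
                 fp_config = fp_config),
            class = "scoring_context")
}

#' Composite filtered score of one molecule
#'
#' `final = raw * [property filter] * [diversity filter]`, where `raw` is the
#' oracle output (0 for invalid molecules). When the molecule passes both
#' filters and `final >= S`, its fingerprint is registered in the
#' diversity-filter memory, so later near neighbors are zeroed.
#'
#' @param record A `molecule_record`.
#' @param context A [scoring_context()].
#' @return List with `final`, `raw`, `property_pass`, `df_pass`.
#' @export
composite_score <- function(record, context) {
  stopifnot(inherits(record, "molecule_record"),
            inherits(context, "scoring_context"))
  if (!isTRUE(record$valid))
    return(list(final = 0, raw = 0, property_pass = FALSE, df_pass = FALSE))
  raw <- context$oracle(record)
  if (!is.numeric(raw) || length(raw) != 1L || is.na(raw) || raw < 0 || raw > 1)
    stop("broken oracle: returned ", deparse(raw), " instead of a number in [0,1]")
  pp <- property_filter(record, context$filters)
  dfp <- if (is.null(context$df)) TRUE else df_check(context$df, record$fingerprint)
  final <- raw * as.numeric(pp) * as.numeric(dfp)
  if (pp && dfp && !is.null(context$df) && final >= context$S)
    df_register_hit(context$df, record$fingerprint)
  list(final = final, raw = raw, property_pass = pp, df_pass = dfp)
}

#' Hit determination
#'
#' A molecule is a hit iff it passes the property filter and its raw oracle
#' score reaches the threshold `S` (inclusive). The diversity filter is
#' deliberately excluded: a genuine hit whose score was suppressed because a
#' near neighbor was found earlier still counts in evaluation -- the full run
#' log is kept precisely so such molecules are not discarded.
#'
#' @param raw Raw oracle score in \[0, 1\].
#' @param property_pass Logical, property-filter outcome.
#' @param S Hit threshold; default 0.5.
#' @return Logical.
#' @export
is_hit <- function(raw, property_pass, S = 0.5) {
  property_pass & raw >= S
}

# ---- key-value config files -------------------------------------------------

#' Read a scoring configuration file
#'
#' INI-style sections: `[filters]` with `mw_min/mw_max/logp_min/logp_max/
#' idio_min/idio_max`, `[df]` with `threshold/enabled`, `[hit]` with `S`.
#' Missing keys keep their defaults, which match the package's reference
#' values exactly.
#'
#' @param path Path to the file.
#' @return List with elements `filters` ([property_filter_config()]), `df`
#'   (a [diversity_filter()] or `NULL` when disabled), and `S`.
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  section <- ""
  vals <- list()
  for (l in ln) {
    if (grepl("^\\[.+\\]$", l)) {
      section <- substr(l, 2L, nchar(l) - 1L)
    } else if (grepl("=", l, fixed = TRUE)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
      vals[[paste0(section, ".", trimws(kv[1L]))]] <- trimws(paste(kv[-1L], collapse = "="))
    } else {
      stop("malformed config line in ", path, ": ", l)
    }
  }
  num <- function(key, default) {
    v <- vals[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  filters <- property_filter_config(
    mw_range = c(num("filters.mw_min", 157), num("filters.mw_max", 761)),
    logp_range = c(num("filters.logp_min", -2.0), num("filters.logp_max", 8.3)),
    idio_range = c(num("filters.idio_min", 0.00), num("filters.idio_max", 0.08)))
  enabled <- vals[["df.enabled"]]
  enabled <- is.null(enabled) || tolower(enabled) %in% c("true", "1", "yes")
  S <- num("hit.S", 0.5)
  df <- if (enabled) diversity_filter(distance_threshold = num("df.threshold", 0.7),
                                      hit_score_threshold = S) else NULL
  list(filters = filters, df = df, S = S)
}
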