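#' Construct a measurement set
#'
#' The central data container: a long table of per-sample analyte
#' concentrations (ng/g wet weight) with left-censoring markers, plus
#' the analyte panel and per-species composition metadata (batch and
#' sample counts, glaze, fat and dry-weight percentages).
#'
#' @param records data.frame with columns `sample_id`, `batch_id`,
#'   `species`, `analyte_id`, `value` (numeric, `NA` when censored),
#'   `censored` (logical).
#' @param panel analyte panel, see [default_panel()].
#' @param species_meta data.frame with one row per species: `species`,
#'   `n_batches`, `n_samples`, `glaze_pct_mean`, `fat_pct_mean`,
#'   `dry_weight_pct_mean` (and optionally their `_sd` columns and
#'   `display_name`).
#' @param batch_meta optional data.frame of per-batch composition
#'   (`batch_id`, `species`, `fat_pct`, `dry_weight_pct`, ...), used by
#'   correlation analyses when available (the simulator attaches it).
#' @return An object of class `measurement_set`.
#' @seealso [validate_measurement_set()], [read_measurements()],
#'   [paper_fixture()], [simulate_measurements()]
#' @export
measurement_set <- function(records, panel = default_panel(),
                            species_meta = NULL, batch_meta = NULL) {
  needed <- c("sample_id", "batch_id", "species", "analyte_id",
              "value", "censored")
  if (!all(needed %in% names(records)))
    stop_fr("records must have columns: %s", paste(needed, collapse = ", "))
  records <- records[needed]
  records$value <- as.numeric(records$value)
  records$censored <- as.logical(records$censored)
  ms <- structure(list(panel = panel, records = records,
                       species_meta = species_meta,
                       batch_meta = batch_meta),
                  class = "measurement_set")
  ms
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set>\n")
  cat(sprintf("  %d records | %d species | %d analytes | %d censored (<LOD)\n",
              nrow(x$records), length(unique(x$records$species)),
              length(unique(x$records$analyte_id)),
              sum(x$records$censored)))
  invisible(x)
}

#' Validate a measurement set
#'
#' Checks the container invariants and returns violations as data, not
#' errors: unresolved analyte ids, negative or missing observed values,
#' numeric values attached to censored markers, duplicated
#' (sample, analyte) keys, and out-of-range composition percentages.
#'
#' @param ms a [measurement_set()].
#' @return data.frame with columns `rule`, `sample_id`, `analyte_id`,
#'   `message`; zero rows when the set is well formed.
#' @export
validate_measurement_set <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  rec <- ms$records
  v <- list()
  add <- function(rule, sample_id, analyte_id, message) {
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, sample_id = sample_id, analyte_id = analyte_id,
      message = message, stringsAsFactors = FALSE)
  }

  unresolved <- !(rec$analyte_id %in% ms$panel$analyte_id)
  for (i in which(unresolved))
    add("unresolved_analyte", rec$sample_id[i], rec$analyte_id[i],
        sprintf("analyte '%s' not in panel", rec$analyte_id[i]))

  bad_obs <- !rec$censored & (is.na(rec$value) | rec$value < 0)
  for (i in which(bad_obs))
    add("invalid_value", rec$sample_id[i], rec$analyte_id[i],
        "observed value missing or negative")

  cens_with_value <- rec$censored & !is.na(rec$value)
  for (i in which(cens_with_value))
    add("censored_with_value", rec$sample_id[i], rec$analyte_id[i],
        "censored record must not carry a numeric value")

  key <- paste(rec$sample_id, rec$analyte_id, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    i <- match(k, key)
    add("duplicate_key", rec$sample_id[i], rec$analyte_id[i],
        "duplicate (sample_id, analyte_id)")
  }

  sm <- ms$species_meta
  if (!is.null(sm)) {
    for (col in intersect(c("fat_pct_mean", "dry_weight_pct_mean"), names(sm))) {
      bad <- !is.na(sm[[col]]) & (sm[[col]] <= 0 | sm[[col]] >= 100)
      for (i in which(bad))
        add("composition_range", sm$species[i], NA_character_,
            sprintf("%s out of (0, 100): %g", col, sm[[col]][i]))
    }
    if (all(c("n_batches", "n_samples") %in% names(sm))) {
      cnt <- table(unique(rec[c("sample_id", "species")])$species)
      for (i in seq_len(nrow(sm))) {
        n_obs <- as.integer(cnt[sm$species[i]] %||% 0)
        if (!is.na(n_obs) && n_obs > sm$n_samples[i])
          add("sample_count", sm$species[i], NA_character_,
              sprintf("%d distinct samples exceed declared %d",
                      n_obs, sm$n_samples[i]))
      }
    }
  }

  if (length(v) == 0L)
    return(data.frame(rule = character(), sample_id = character(),
                      analyte_id = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

CENSOR_TOKEN <- "<LOD"

#' Read and write measurement CSV files
#'
#' Long-format CSV interchange: columns `sample_id`, `batch_id`,
#' `species`, `analyte_id`, `value`, with censored values encoded as the
#' literal token `"<LOD"`. Writing and re-reading a set reproduces its
#' records field-for-field, censored markers included.
#'
#' @param path file path.
#' @param panel analyte panel used to resolve ids on read.
#' @param species_meta,batch_meta optional metadata passed through to
#'   the constructed [measurement_set()].
#' @return `read_measurements()`: a [measurement_set()].
#' @export
read_measurements <- function(path, panel = default_panel(),
                              species_meta = NULL, batch_meta = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  needed <- c("sample_id", "batch_id", "species", "analyte_id", "value")
  if (!all(needed %in% names(raw)))
    stop_fr("measurement CSV must have columns: %s",
            paste(needed, collapse = ", "))
  censored <- raw$value == CENSOR_TOKEN
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- !censored & is.na(value)
  if (any(bad))
    stop_fr("malformed value(s) at data line(s) %s of %s",
            paste(utils::head(which(bad), 5L), collapse = ", "), path)
  value[censored] <- NA_real_
  measurement_set(
    data.frame(sample_id = raw$sample_id, batch_id = raw$batch_id,
               species = raw$species, analyte_id = raw$analyte_id,
               value = value, censored = censored,
               stringsAsFactors = FALSE),
    panel = panel, species_meta = species_meta, batch_meta = batch_meta)
}

#' @rdname read_measurements
#' @param ms a [measurement_set()] to serialize.
#' @return `write_measurements()`: the path, invisibly.
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  rec <- ms$records
  out <- data.frame(sample_id = rec$sample_id, batch_id = rec$batch_id,
                    species = rec$species, analyte_id = rec$analyte_id,
                    value = ifelse(rec$censored, CENSOR_TOKEN,
                                   format(rec$value, trim = TRUE,
                                          scientific = FALSE, digits = 15)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
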