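#' Run the full risk assessment
#'
#' Orchestrates every stage on one measurement set: per-species summary
#' statistics, endosulfan metabolite shares, pesticide LADD/HQ
#' screening, dioxin-like PCB TEQ with weekly-intake assessment against
#' both TWI thresholds, Duncan's between-species test per analyte
#' (where replication allows), and composition correlations. All
#' sections are computed from the same substituted concentrations, so
#' they are cross-consistent: the intake section's `wi` equals
#' `weekly_intake(teq, adc_teq, bw)` applied to the TEQ section of the
#' same report. Internal values are kept at full precision; rounding
#' happens only at serialization.
#'
#' @param ms a [measurement_set()], or a path to a measurement CSV.
#' @param ref [reference_tables][read_reference_config], or a path to a
#'   YAML reference config.
#' @param policy a [censoring_policy()].
#' @return list of class `risk_report` with elements `summary`,
#'   `endosulfan`, `hazard`, `teq`, `intake`, `duncan`, `correlation`
#'   and a `provenance` block (censoring policy, intake constants, TWI
#'   thresholds, package version).
#' @export
run_full_assessment <- function(ms, ref = default_reference_tables(),
                                policy = censoring_policy()) {
  if (is.character(ms)) ms <- read_measurements(ms)
  if (is.character(ref)) ref <- read_reference_config(ref)
  stopifnot(inherits(ms, "measurement_set"), inherits(ref, "reference_tables"))
  if (nrow(ms$records) == 0L)
    stop_fr("empty measurement set: nothing to assess")
  violations <- validate_measurement_set(ms)
  if (nrow(violations) > 0L)
    stop_fr("measurement set fails validation (%d violation(s)); first: %s",
            nrow(violations), violations$message[1])

  summary_tab <- summarize_measurements(ms, policy)
  hazard_tab <- screen_species(ms, ref, policy)
  teq_tab <- teq_by_species(ms, ref, policy)
  wi <- weekly_intake(teq_tab$teq, ref$adc_teq, ref$bw)
  intake_tab <- cbind(species = teq_tab$species, teq = teq_tab$teq,
                      twi_assessment(wi, ref))
  duncan_tab <- duncan_by_analyte(ms, policy)
  corr_tab <- if (is.null(ms$batch_meta) && is.null(ms$species_meta)) {
    data.frame(analyte_id = character(), covariate = character(),
               r = numeric(), n = integer(), stringsAsFactors = FALSE)
  } else {
    correlate_with_composition(ms, policy)
  }
  endos_tab <- endosulfan_shares(ms, policy)

  structure(list(
    summary = summary_tab,
    endosulfan = endos_tab,
    hazard = hazard_tab,
    teq = teq_tab,
    intake = intake_tab,
    duncan = duncan_tab,
    correlation = corr_tab,
    provenance = list(
      censoring_policy = policy$mode,
      adc_hq = ref$adc_hq, adc_teq = ref$adc_teq, bw = ref$bw,
      twi_old = ref$twi_old, twi_new = ref$twi_new,
      n_records = nrow(ms$records),
      package_version = as.character(utils::packageVersion("fishrisk")))
  ), class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report>\n")
  cat(sprintf("  species: %s\n", paste(x$intake$species, collapse = ", ")))
  cat(sprintf("  max HQ: %.4g | WI range: %.2f-%.2f pg-TEQ/kg bw/week\n",
              max(x$hazard$hq, na.rm = TRUE),
              min(x$intake$wi), max(x$intake$wi)))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  df
}

#' Write a risk report to disk
#'
#' One CSV per section plus a human-readable `summary.txt`. Table rows
#' are already sorted by species then analyte key; CSVs round to the
#' reporting precision of the corresponding published tables (CV two
#' decimals, shares to integers, correlations three decimals; dose and
#' intake quantities are written at full precision). Re-reading a CSV
#' reproduces the rounded table.
#'
#' @param report a `risk_report` from [run_full_assessment()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "risk_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_fr("cannot create output directory '%s'", out_dir)
  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  sm <- report$summary
  sm$cv <- round(sm$cv, 2)
  put(sm, "summary_stats.csv")
  en <- report$endosulfan
  en$sulfate_share_pct <- round(en$sulfate_share_pct)
  put(en, "endosulfan_shares.csv")
  put(report$hazard, "hazard.csv")
  put(round_df(report$teq, 6), "teq.csv")
  it <- report$intake
  it$pct_of_twi_old <- round(it$pct_of_twi_old)
  put(it, "intake.csv")
  put(report$duncan, "duncan.csv")
  cr <- report$correlation
  cr$r <- round(cr$r, 3)
  put(cr, "correlation.csv")

  prov <- report$provenance
  lines <- c(
    "Fish-product organochlorine risk assessment",
    "===========================================",
    sprintf("censoring policy: <LOD -> %s", prov$censoring_policy),
    sprintf("ADC: %.2f g/day (HQ path), %.2f g/day (TEQ path); BW: %g kg",
            prov$adc_hq, prov$adc_teq, prov$bw),
    sprintf("TWI: %g (former) / %g (current) pg-TEQ/kg bw/week",
            prov$twi_old, prov$twi_new),
    sprintf("records assessed: %d | fishrisk %s",
            prov$n_records, prov$package_version),
    "",
    sprintf("max hazard quotient: %.4g (threshold 1.0)%s",
            max(report$hazard$hq, na.rm = TRUE),
            if (any(report$hazard$exceeds)) " EXCEEDED" else ""),
    "",
    "weekly intake vs TWI:")
  for (i in seq_len(nrow(it))) {
    lines <- c(lines, sprintf(
      "  %-16s TEQ %6.3f pg/g  WI %6.2f  %3.0f%% of former TWI%s  %4.2fx current TWI%s",
      it$species[i], it$teq[i], it$wi[i], it$pct_of_twi_old[i],
      if (it$exceeds_old[i]) " EXCEEDS" else "",
      it$ratio_to_twi_new[i],
      if (it$exceeds_new[i]) " EXCEEDS" else ""))
  }
  txt <- file.path(out_dir, "summary.txt")
  writeLines(lines, txt)
  files <- c(files, txt)
  invisible(files)
}
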