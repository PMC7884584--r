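#' Lifetime average daily dose (LADD)
#'
#' \deqn{LADD = \frac{C \cdot ADC}{BW}}
#' with C the mean concentration of the pesticide in fish (ng/g wet
#' weight), ADC the average daily fish consumption (g/day) and BW the
#' body weight (kg). The ng-to-mg bridge (1e-6) is applied here so the
#' result is in mg/kg/day, the unit of the reference doses.
#'
#' @param conc mean concentration, ng/g wet weight (>= 0). Vectorized.
#' @param adc average daily consumption, g/day (> 0).
#' @param bw body weight, kg (> 0).
#' @return dose in mg/kg/day.
#' @examples
#' lifetime_average_daily_dose(0.5069, adc = 34.30, bw = 70)
#' @export
lifetime_average_daily_dose <- function(conc, adc, bw) {
  if (any(is.na(conc)) || any(conc < 0))
    stop_fr("concentrations must be present and >= 0")
  assert_scalar_number(adc, "adc", 0, strict = TRUE)
  assert_scalar_number(bw, "bw", 0, strict = TRUE)
  conc * 1e-6 * adc / bw
}

#' Hazard quotient (HQ)
#'
#' \deqn{HQ = LADD / RfD.} A value above 1.0 flags a dose above the
#' chronic oral reference dose, i.e. potential harm.
#'
#' @param ladd dose in mg/kg/day (>= 0). Vectorized.
#' @param rfd chronic oral reference dose, mg/kg/day (> 0); recycled
#'   against `ladd`.
#' @param analyte_id optional label(s) used in error messages.
#' @return list with `hq` and logical `exceeds` (`hq > 1`).
#' @export
hazard_quotient <- function(ladd, rfd, analyte_id = NULL) {
  if (any(is.na(ladd)) || any(ladd < 0))
    stop_fr("ladd must be present and >= 0")
  if (any(is.na(rfd)) || any(rfd <= 0)) {
    bad <- which(is.na(rfd) | rfd <= 0)
    lab <- if (!is.null(analyte_id)) paste(analyte_id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop_fr("missing or non-positive RfD for: %s", lab)
  }
  hq <- ladd / rfd
  list(hq = hq, exceeds = hq > 1.0)
}

#' Hazard screening of pesticide residues per species
#'
#' For every (species, OCP analyte) pair: mean substituted
#' concentration, LADD, RfD, HQ and the exceedance flag, plus one
#' aggregate row per species (`analyte_id = "TOTAL"`) carrying the sum
#' of the per-analyte doses and quotients — the conservative screening
#' aggregate. Detected analytes with no RfD entry are kept in the
#' table with `hq = NA` and `incomplete = TRUE` rather than dropped.
#'
#' @param ms a [measurement_set()].
#' @param ref [reference_tables][read_reference_config] providing
#'   `rfd`, `adc_hq`, `bw`.
#' @param policy a [censoring_policy()].
#' @return data.frame `species`, `analyte_id`, `c_mean` (ng/g),
#'   `ladd`, `rfd`, `hq`, `exceeds`, `incomplete`.
#' @export
screen_species <- function(ms, ref = default_reference_tables(),
                           policy = censoring_policy()) {
  stopifnot(inherits(ms, "measurement_set"), inherits(ref, "reference_tables"))
  ocps <- intersect(ocp_ids(ms$panel), unique(ms$records$analyte_id))
  if (!length(ocps))
    stop_fr("measurement set contains no pesticide records")
  sm <- summarize_measurements(ms, policy, analyte_id = ocps)
  rfd <- unname(ref$rfd[sm$analyte_id])
  ladd <- lifetime_average_daily_dose(sm$mean, ref$adc_hq, ref$bw)
  hq <- ifelse(!is.na(rfd) & rfd > 0, ladd / unname(rfd), NA_real_)
  per <- data.frame(species = sm$species, analyte_id = sm$analyte_id,
                    c_mean = sm$mean, ladd = ladd, rfd = unname(rfd),
                    hq = hq, exceeds = !is.na(hq) & hq > 1.0,
                    incomplete = is.na(hq) & sm$mean > 0,
                    stringsAsFactors = FALSE)
  totals <- lapply(unique(per$species), function(sp) {
    sub <- per[per$species == sp, , drop = FALSE]
    data.frame(species = sp, analyte_id = "TOTAL",
               c_mean = sum(sub$c_mean), ladd = sum(sub$ladd),
               rfd = NA_real_, hq = sum(sub$hq, na.rm = TRUE),
               exceeds = sum(sub$hq, na.rm = TRUE) > 1.0,
               incomplete = any(sub$incomplete), stringsAsFactors = FALSE)
  })
  out <- rbind(per, do.call(rbind, totals))
  out <- out[order(out$species, out$analyte_id == "TOTAL", out$analyte_id), ]
  rownames(out) <- NULL
  out
}
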