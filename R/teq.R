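#' Toxic equivalency (TEQ) of a dioxin-like PCB mixture
#'
#' \deqn{TEQ = \sum_i C_{PCB_i} \cdot TEF_i}
#' Each congener concentration (ng/g wet weight) is multiplied by its
#' WHO 2005 toxicity equivalency factor; the pg-per-ng factor 1000 is
#' applied here, so the TEQ and every downstream intake quantity are in
#' pg-TEQ/g wet weight. Censored entries must be substituted upstream
#' (they contribute 0 under the default policy).
#'
#' @param congener_conc named numeric vector, ng/g wet weight, >= 0;
#'   names are congener ids (`PCB77`, ...).
#' @param tef named numeric TEF map covering every congener supplied.
#' @return list of class `teq_result`: `teq` (pg-TEQ/g) and
#'   `contributions` (named, pg-TEQ/g).
#' @examples
#' toxic_equivalency(c(PCB126 = 0.02),
#'                   default_reference_tables()$tef)$teq  # 2 pg-TEQ/g
#' @export
toxic_equivalency <- function(congener_conc, tef) {
  if (length(congener_conc) == 0L)
    return(structure(list(teq = 0, contributions = numeric(0)),
                     class = "teq_result"))
  if (is.null(names(congener_conc)) || any(!nzchar(names(congener_conc))))
    stop_fr("congener concentrations must be named")
  if (any(is.na(congener_conc)) || any(congener_conc < 0))
    stop_fr("congener concentrations must be present and >= 0")
  missing <- setdiff(names(congener_conc), names(tef))
  if (length(missing))
    stop_fr("no TEF for congener(s): %s", paste(missing, collapse = ", "))
  contrib <- congener_conc * tef[names(congener_conc)] * 1000
  structure(list(teq = sum(contrib), contributions = contrib),
            class = "teq_result")
}

#' Per-species TEQ from a measurement set
#'
#' Mean substituted concentration of each dioxin-like congener per
#' species, TEF-weighted and summed.
#'
#' @inheritParams screen_species
#' @return data.frame `species`, `teq` (pg-TEQ/g wet weight), plus one
#'   column per dioxin-like congener with its contribution.
#' @export
teq_by_species <- function(ms, ref = default_reference_tables(),
                           policy = censoring_policy()) {
  stopifnot(inherits(ms, "measurement_set"), inherits(ref, "reference_tables"))
  dl <- intersect(dl_pcb_ids(ms$panel), unique(ms$records$analyte_id))
  if (!length(dl))
    stop_fr("measurement set contains no dioxin-like PCB records")
  sm <- summarize_measurements(ms, policy, analyte_id = dl)
  rows <- lapply(unique(sm$species), function(sp) {
    sub <- sm[sm$species == sp, , drop = FALSE]
    conc <- stats::setNames(sub$mean, sub$analyte_id)
    res <- toxic_equivalency(conc, ref$tef)
    cbind(data.frame(species = sp, teq = res$teq, stringsAsFactors = FALSE),
          as.data.frame(as.list(res$contributions)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimated weekly intake of TEQ
#'
#' \deqn{WI = TEQ \cdot ADC \cdot 7 / BW}
#' in pg-TEQ per kg body weight per week (week = exactly 7 days).
#'
#' @param teq pg-TEQ/g wet weight (>= 0). Vectorized.
#' @param adc daily fish consumption, g/day (> 0); the TEQ path default
#'   is 34.19 g/day.
#' @param bw body weight, kg (> 0).
#' @return weekly intake, pg-TEQ/kg bw/week.
#' @examples
#' weekly_intake(1.79, adc = 34.19, bw = 70)  # 6.12
#' @export
weekly_intake <- function(teq, adc, bw) {
  if (any(is.na(teq)) || any(teq < 0))
    stop_fr("teq must be present and >= 0")
  assert_scalar_number(adc, "adc", 0, strict = TRUE)
  assert_scalar_number(bw, "bw", 0, strict = TRUE)
  teq * adc * 7 / bw
}

#' Compare a weekly intake against the TWI thresholds
#'
#' Relates an estimated weekly intake to the former tolerable weekly
#' intake (14 pg-TEQ/kg bw/week) as a percentage and to the current one
#' (2 pg-TEQ/kg bw/week) as a ratio, with exceedance flags for both.
#'
#' @param wi weekly intake, pg-TEQ/kg bw/week (>= 0). Vectorized.
#' @param ref [reference_tables][read_reference_config] providing
#'   `twi_old` and `twi_new`.
#' @return data.frame `wi`, `pct_of_twi_old` (= 100 wi / twi_old),
#'   `ratio_to_twi_new` (= wi / twi_new), `exceeds_old`, `exceeds_new`.
#' @examples
#' twi_assessment(c(6.12, 7.45))
#' @export
twi_assessment <- function(wi, ref = default_reference_tables()) {
  if (any(is.na(wi)) || any(wi < 0))
    stop_fr("wi must be present and >= 0")
  data.frame(wi = wi,
             pct_of_twi_old = 100 * wi / ref$twi_old,
             ratio_to_twi_new = wi / ref$twi_new,
             exceeds_old = wi > ref$twi_old,
             exceeds_new = wi > ref$twi_new)
}

#' Annual consumption to daily intake
#'
#' kg per person per year to g per person per day, using a 365-day
#' year: `annual_kg * 1000 / 365`.
#'
#' @param annual_kg annual consumption, kg/person/year (>= 0).
#' @param digits decimal places for reporting (default 2); `NULL` for
#'   the unrounded value.
#' @return daily intake, g/day/person.
#' @examples
#' annual_to_daily(12.48)  # 34.19
#' @export
annual_to_daily <- function(annual_kg, digits = 2) {
  if (any(is.na(annual_kg)) || any(annual_kg < 0))
    stop_fr("annual_kg must be present and >= 0")
  g <- annual_kg * 1000 / 365
  if (is.null(digits)) g else round(g, digits)
}
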