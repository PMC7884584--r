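#' Censored-value substitution policy
#'
#' Concentrations below the limit of detection (LOD) are left-censored:
#' the record carries no numeric value, only the information "below this
#' analyte's LOD". Before any arithmetic (means, doses, TEQs) a
#' substitution policy replaces each censored record by 0, LOD/2, or
#' LOD. The package default is zero-substitution, which treats
#' non-detects as absent; LOD/2 and LOD give progressively more
#' conservative (higher) exposure estimates, so for any fixed LOD the
#' three policies are ordered: zero <= half_lod <= lod.
#'
#' @param mode one of `"zero"`, `"half_lod"`, `"lod"`.
#' @return An object of class `censoring_policy`.
#' @examples
#' censoring_policy("half_lod")
#' @export
censoring_policy <- function(mode = c("zero", "half_lod", "lod")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "censoring_policy")
}

#' @export
print.censoring_policy <- function(x, ...) {
  cat("<censoring_policy> <LOD ->",
      switch(x$mode, zero = "0", half_lod = "LOD/2", lod = "LOD"), "\n")
  invisible(x)
}

#' Substitute censored concentrations
#'
#' Applies a [censoring_policy()] to measurement records: observed
#' values pass through unchanged; censored values are replaced by 0,
#' LOD/2 or LOD using each analyte's detection limit from the panel.
#'
#' @param records a data.frame with columns `analyte_id`, `value`
#'   (numeric, `NA` when censored) and `censored` (logical), e.g. the
#'   `records` element of a [measurement_set()].
#' @param panel analyte panel ([default_panel()]) supplying per-analyte
#'   LODs.
#' @param policy a [censoring_policy()].
#' @return Numeric vector of substituted concentrations, ng/g wet
#'   weight, one per record.
#' @examples
#' rec <- data.frame(analyte_id = c("aHCH", "aHCH"),
#'                   value = c(0.5069, NA),
#'                   censored = c(FALSE, TRUE))
#' substitute_censored(rec, default_panel(), censoring_policy("half_lod"))
#' @export
substitute_censored <- function(records, panel, policy = censoring_policy()) {
  stopifnot(inherits(policy, "censoring_policy"))
  if (!all(c("analyte_id", "value", "censored") %in% names(records)))
    stop_fr("records must have columns analyte_id, value, censored")
  idx <- panel_lookup(panel, records$analyte_id)
  obs <- records$value
  if (any(!records$censored & (is.na(obs) | obs < 0)))
    stop_fr("observed values must be present and >= 0")
  lod <- panel$lod[idx]
  sub <- switch(policy$mode,
                zero = 0 * lod,
                half_lod = lod / 2,
                lod = lod)
  ifelse(records$censored, sub, obs)
}
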