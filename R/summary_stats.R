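#' Coefficient of variation
#'
#' `100 * sd / mean`, reported to two decimal places as in the summary
#' tables. The sample standard deviation (n-1 denominator) is assumed
#' throughout the package: the printed mean/SD/CV triples (e.g. mean
#' 0.5069, SD 0.1562, CV 30.82 for alpha-HCH in Nile tilapia) are
#' mutually consistent under that convention.
#'
#' @param mean group mean, must be > 0.
#' @param sd sample standard deviation, must be >= 0.
#' @param digits decimal places for reporting (default 2); use
#'   `digits = NULL` for the unrounded value.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(0.5069, 0.1562)  # 30.82
#' @export
coefficient_of_variation <- function(mean, sd, digits = 2) {
  assert_scalar_number(mean, "mean", 0, strict = TRUE)
  assert_scalar_number(sd, "sd", 0)
  cv <- 100 * sd / mean
  if (is.null(digits)) cv else round(cv, digits)
}

summarize_values <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1L) stats::sd(x) else 0
  list(n = n, mean = m, sd = s, min = min(x), max = max(x),
       median = stats::median(x),
       cv = if (m > 0) 100 * s / m else NA_real_,
       cv_undefined = m <= 0)
}

#' Per-species summary statistics on substituted concentrations
#'
#' Computes n, mean, sample SD, min, max, median and CV for every
#' (species, analyte) pair present in the set, after applying the
#' censored-value substitution policy. Under zero-substitution an
#' all-censored group has mean 0 and its CV is flagged undefined
#' (`NA`).
#'
#' @param ms a [measurement_set()].
#' @param policy a [censoring_policy()]; default zero-substitution.
#' @param species,analyte_id optional filters; by default all pairs are
#'   summarized.
#' @return data.frame with columns `species`, `analyte_id`, `n`,
#'   `mean`, `sd`, `min`, `max`, `median`, `cv`, `cv_undefined`, sorted
#'   by species then analyte.
#' @export
summarize_measurements <- function(ms, policy = censoring_policy(),
                                   species = NULL, analyte_id = NULL) {
  stopifnot(inherits(ms, "measurement_set"))
  rec <- ms$records
  if (!is.null(species)) rec <- rec[rec$species %in% species, , drop = FALSE]
  if (!is.null(analyte_id))
    rec <- rec[rec$analyte_id %in% analyte_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_fr("no records for the requested species/analyte selection")
  rec$subst <- substitute_censored(rec, ms$panel, policy)
  keys <- unique(rec[c("species", "analyte_id")])
  keys <- keys[order(keys$species, keys$analyte_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    x <- rec$subst[rec$species == keys$species[i] &
                   rec$analyte_id == keys$analyte_id[i]]
    st <- summarize_values(x)
    data.frame(species = keys$species[i], analyte_id = keys$analyte_id[i],
               n = st$n, mean = st$mean, sd = st$sd, min = st$min,
               max = st$max, median = st$median, cv = st$cv,
               cv_undefined = st$cv_undefined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Share of one component in a metabolite profile
#'
#' For a set of related compounds (e.g. endosulfan alpha, beta and the
#' sulfate metabolite) returns the percentage that one component
#' contributes to the summed mean concentration. Censored components
#' enter as their substituted values (0 under the default policy).
#'
#' @param component_means named numeric vector of mean concentrations
#'   (ng/g), all >= 0, summing to > 0.
#' @param numerator name of the component whose share is requested.
#' @return Share in percent (unrounded; the tables report it rounded to
#'   the nearest integer).
#' @examples
#' metabolite_share(c(endosulfan_a = 0.0285, endosulfan_b = 0.0293,
#'                    endosulfan_sulfate = 0.1073), "endosulfan_sulfate")
#' @export
metabolite_share <- function(component_means, numerator) {
  if (!numerator %in% names(component_means))
    stop_fr("numerator '%s' not among components", numerator)
  if (any(component_means < 0))
    stop_fr("component means must be >= 0")
  total <- sum(component_means)
  if (total <= 0)
    stop_fr("total of component means is zero; share undefined")
  100 * component_means[[numerator]] / total
}

#' Endosulfan-sulfate share per species
#'
#' Convenience wrapper: per-species endosulfan profile (alpha, beta,
#' sulfate means on substituted values) and the sulfate share of total
#' endosulfan.
#'
#' @inheritParams summarize_measurements
#' @return data.frame `species`, `endosulfan_a`, `endosulfan_b`,
#'   `endosulfan_sulfate` (mean ng/g), `sulfate_share_pct`.
#' @export
endosulfan_shares <- function(ms, policy = censoring_policy()) {
  comp <- c("endosulfan_a", "endosulfan_b", "endosulfan_sulfate")
  sm <- summarize_measurements(ms, policy, analyte_id = comp)
  species <- unique(sm$species)
  rows <- lapply(species, function(sp) {
    means <- stats::setNames(
      sm$mean[sm$species == sp][match(comp, sm$analyte_id[sm$species == sp])],
      comp)
    means[is.na(means)] <- 0
    data.frame(species = sp, endosulfan_a = means[["endosulfan_a"]],
               endosulfan_b = means[["endosulfan_b"]],
               endosulfan_sulfate = means[["endosulfan_sulfate"]],
               sulfate_share_pct = metabolite_share(means, "endosulfan_sulfate"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two series
#'
#' Product-moment correlation with the preconditions of the composition
#' analyses enforced: equal lengths, at least three pairs, nonzero
#' variance in both series.
#'
#' @param xs,ys numeric vectors of equal length (n >= 3).
#' @return list with `r` (in \[-1, 1\]) and `n`.
#' @export
pearson_correlation <- function(xs, ys) {
  if (length(xs) != length(ys))
    stop_fr("series lengths differ (%d vs %d)", length(xs), length(ys))
  if (length(xs) < 3L)
    stop_fr("need at least 3 pairs, got %d", length(xs))
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop_fr("degenerate series: zero variance")
  list(r = stats::cor(xs, ys), n = length(xs))
}

#' Correlation of analyte content with composition covariates
#'
#' Pearson correlation between per-batch mean substituted
#' concentrations and the dry-mass or fat percentage, the finest level
#' at which composition is available. When the set carries per-batch
#' composition (`batch_meta`, attached by the simulator) it is used;
#' otherwise the per-species values are replicated over batches.
#'
#' @inheritParams summarize_measurements
#' @param covariates which covariates to use (columns `dry_weight_pct`,
#'   `fat_pct`).
#' @return data.frame `analyte_id`, `covariate`, `r`, `n`.
#' @export
correlate_with_composition <- function(ms, policy = censoring_policy(),
                                       covariates = c("dry_weight_pct",
                                                      "fat_pct")) {
  stopifnot(inherits(ms, "measurement_set"))
  rec <- ms$records
  rec$subst <- substitute_censored(rec, ms$panel, policy)
  agg <- stats::aggregate(subst ~ species + batch_id + analyte_id,
                          data = rec, FUN = mean)
  bm <- ms$batch_meta
  if (is.null(bm)) {
    sm <- ms$species_meta
    if (is.null(sm))
      stop_fr("no batch_meta or species_meta available for covariates")
    batches <- unique(rec[c("species", "batch_id")])
    bm <- data.frame(batches,
                     fat_pct = sm$fat_pct_mean[match(batches$species,
                                                     sm$species)],
                     dry_weight_pct = sm$dry_weight_pct_mean[
                       match(batches$species, sm$species)],
                     stringsAsFactors = FALSE)
  }
  agg <- merge(agg, bm, by = c("species", "batch_id"))
  rows <- list()
  for (a in sort(unique(agg$analyte_id))) {
    sub <- agg[agg$analyte_id == a, , drop = FALSE]
    for (cv_name in covariates) {
      ok <- nrow(sub) >= 3L && stats::sd(sub$subst) > 0 &&
        stats::sd(sub[[cv_name]]) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        analyte_id = a,
        covariate = if (cv_name == "fat_pct") "fat" else "dry_mass",
        r = if (ok) stats::cor(sub$subst, sub[[cv_name]]) else NA_real_,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
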