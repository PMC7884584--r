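#' Simulation recipe for batch-structured censored residue data
#'
#' Defines the distributional shape of a synthetic measurement set:
#' per (species, analyte) a target mean (ng/g wet weight) and target
#' coefficient of variation (percent), per species a batch count and
#' composition moments, and globally the number of samples per batch
#' (10, the replication of the emulated study), the distribution
#' family, the between-batch share of the dispersion, and the
#' correlation tying composition covariates to batch-level
#' contamination.
#'
#' The default family is lognormal: residue concentrations are positive
#' and right-skewed, and target CVs up to 243 percent rule out
#' normality (a truncated normal cannot exceed CV 100 percent and is
#' offered only for sensitivity checks at moderate CVs). The total
#' dispersion is split multiplicatively: the between-batch CV defaults
#' to half the target CV, and the within-batch CV is chosen so that
#' `(1 + cv^2) = (1 + cv_b^2)(1 + cv_w^2)`, which makes the overall
#' mean and CV match the targets exactly under the lognormal family.
#'
#' @param scenarios data.frame with columns `species`, `analyte_id`,
#'   `target_mean`, `target_cv` (percent), `censored` (logical: cell is
#'   wholly below LOD). Defaults to [table_scenarios()].
#' @param species_meta per-species data.frame (see
#'   [fixture_composition()]); needs `species`, `n_batches`, and the
#'   composition moment columns.
#' @param samples_per_batch replicates per batch; default 10.
#' @param family `"lognormal"` (default) or `"truncated_normal"`.
#' @param between_batch_cv_ratio between-batch CV as a fraction of the
#'   target CV; default 0.5.
#' @param composition_correlation correlation between the per-batch
#'   contamination latent and the composition covariates; default 0.4
#'   (mid-range of the published analyte-composition correlations).
#' @param seed integer seed stored with the recipe.
#' @return list of class `simulation_spec`.
#' @seealso [simulate_measurements()]
#' @export
simulation_spec <- function(scenarios = table_scenarios(),
                            species_meta = fixture_composition(),
                            samples_per_batch = 10L,
                            family = c("lognormal", "truncated_normal"),
                            between_batch_cv_ratio = 0.5,
                            composition_correlation = 0.4,
                            seed = 1L) {
  family <- match.arg(family)
  needed <- c("species", "analyte_id", "target_mean", "target_cv", "censored")
  if (!all(needed %in% names(scenarios)))
    stop_fr("scenarios must have columns: %s", paste(needed, collapse = ", "))
  obs <- scenarios[!scenarios$censored, , drop = FALSE]
  if (any(is.na(obs$target_mean)) || any(obs$target_mean < 0))
    stop_fr("target_mean must be >= 0 for observed scenarios")
  if (any(obs$target_mean == 0 & obs$target_cv > 0))
    stop_fr("impossible scenario: mean 0 with positive CV")
  if (any(is.na(obs$target_cv)) || any(obs$target_cv < 0))
    stop_fr("target_cv must be >= 0")
  if (family == "truncated_normal" && any(obs$target_cv >= 100))
    stop_fr("truncated normal cannot reach CV >= 100%%; use lognormal")
  if (samples_per_batch < 1L)
    stop_fr("samples_per_batch must be >= 1")
  if (!all(scenarios$species %in% species_meta$species))
    stop_fr("scenario species missing from species_meta")
  structure(list(scenarios = scenarios, species_meta = species_meta,
                 samples_per_batch = as.integer(samples_per_batch),
                 family = family,
                 between_batch_cv_ratio = between_batch_cv_ratio,
                 composition_correlation = composition_correlation,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Scenario table from the packaged study summaries
#'
#' One scenario per (species, analyte): pesticide cells take the
#' published mean and CV; wholly `<LOD` cells become all-censored
#' scenarios. PCB congener cells (optional) take the published means
#' with a common nominal CV, since the published congener dispersions
#' are not on a usable basis.
#'
#' @param include_pcb also emit PCB congener scenarios; default TRUE.
#' @param pcb_cv nominal CV (percent) for PCB scenarios; default 40.
#' @return data.frame suitable as the `scenarios` argument of
#'   [simulation_spec()].
#' @export
table_scenarios <- function(include_pcb = TRUE, pcb_cv = 40) {
  ocp <- fixture_ocp_summary()
  out <- data.frame(species = ocp$species, analyte_id = ocp$analyte_id,
                    target_mean = ocp$mean, target_cv = ocp$cv,
                    censored = ocp$mean_censored, stringsAsFactors = FALSE)
  if (include_pcb) {
    pcb <- fixture_pcb_means()
    out <- rbind(out, data.frame(
      species = pcb$species, analyte_id = pcb$analyte_id,
      target_mean = pcb$mean,
      target_cv = ifelse(pcb$mean_censored, NA_real_, pcb_cv),
      censored = pcb$mean_censored, stringsAsFactors = FALSE))
  }
  out
}

# Moments of a normal(mu, sig) truncated to (0, Inf).
truncnorm_moments <- function(mu, sig) {
  a <- -mu / sig
  z <- 1 - stats::pnorm(a)
  lam <- stats::dnorm(a) / z
  m <- mu + sig * lam
  v <- sig^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Find (mu, sig) so the truncated-at-zero normal has the target mean/sd.
calibrate_truncnorm <- function(m, s) {
  if (s == 0) return(c(mu = m, sig = 0))
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]))
    (mo["mean"] - m)^2 / m^2 + (mo["sd"] - s)^2 / s^2
  }
  fit <- stats::nlminb(c(m, log(s)), obj)
  if (fit$objective > 1e-8)
    stop_fr("cannot calibrate truncated normal to mean %g, sd %g", m, s)
  c(mu = fit$par[1], sig = exp(fit$par[2]))
}

rtruncnorm0 <- function(n, mu, sig) {
  if (sig == 0) return(rep(mu, n))
  p0 <- stats::pnorm(0, mu, sig)
  stats::qnorm(stats::runif(n, p0, 1), mu, sig)
}

#' Simulate a batch-structured, left-censored measurement set
#'
#' Hierarchical draw per (species, analyte): a latent per-batch level
#' (lognormal multiplier with the between-batch CV, correlated with
#' the batch composition covariates through a shared standard-normal
#' batch factor), then per-sample values around the batch level with
#' the within-batch CV. Draws that fall below the analyte's LOD are
#' emitted as censored records carrying no numeric value. All-censored
#' scenarios emit censored records directly. Identical seeds give
#' identical output.
#'
#' @param spec a [simulation_spec()].
#' @param seed overrides `spec$seed` when given.
#' @param apply_censoring emit draws below the LOD as censored records
#'   (default). Set `FALSE` to emit every draw as observed — used when
#'   checking the generator's distributional calibration, where
#'   substituting censored values would bias the recovered moments for
#'   analytes whose mean sits close to the LOD.
#' @return list with `measurements` (a [measurement_set()] whose
#'   `batch_meta` holds the drawn per-batch composition) and `truth`
#'   (the spec plus realized per-batch latent means, for recovery
#'   testing; never written into the measurement CSV).
#' @examples
#' sc <- data.frame(species = "nile_tilapia", analyte_id = "aHCH",
#'                  target_mean = 0.5069, target_cv = 30.82,
#'                  censored = FALSE)
#' sim <- simulate_measurements(simulation_spec(sc, seed = 7))
#' sim$measurements
#' @export
simulate_measurements <- function(spec, seed = NULL, apply_censoring = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  panel <- default_panel()
  rho <- spec$composition_correlation
  if (rho < 0 || rho >= 1)
    stop_fr("composition_correlation must be in [0, 1)")
  # composition and contamination each load sqrt(rho) on a shared batch
  # factor, so their pairwise correlation is rho on the latent scale
  lam <- sqrt(rho)
  spb <- spec$samples_per_batch

  rec_list <- list()
  truth_list <- list()
  bm_list <- list()
  species_order <- spec$species_meta$species
  for (sp in species_order) {
    scen <- spec$scenarios[spec$scenarios$species == sp, , drop = FALSE]
    if (nrow(scen) == 0L) next
    meta <- spec$species_meta[spec$species_meta$species == sp, , drop = FALSE]
    nb <- as.integer(meta$n_batches)
    batch_id <- sprintf("%s_B%02d", sp, seq_len(nb))
    z_batch <- stats::rnorm(nb)

    draw_comp <- function(mean_col, sd_col) {
      mu <- meta[[mean_col]] %||% NA_real_
      sdv <- meta[[sd_col]] %||% 0
      if (is.na(mu)) return(rep(NA_real_, nb))
      e <- stats::rnorm(nb)
      pmin(pmax(mu + sdv * (lam * z_batch + sqrt(1 - lam^2) * e), 1e-3),
           99.9)
    }
    bm_list[[sp]] <- data.frame(
      species = sp, batch_id = batch_id,
      glaze_pct = draw_comp("glaze_pct_mean", "glaze_pct_sd"),
      fat_pct = draw_comp("fat_pct_mean", "fat_pct_sd"),
      dry_weight_pct = draw_comp("dry_weight_pct_mean", "dry_weight_pct_sd"),
      stringsAsFactors = FALSE)

    for (i in seq_len(nrow(scen))) {
      aid <- scen$analyte_id[i]
      lod <- panel$lod[panel_lookup(panel, aid)]
      sample_id <- sprintf("%s_S%02d", rep(batch_id, each = spb),
                           rep(seq_len(spb), nb))
      if (scen$censored[i]) {
        rec_list[[length(rec_list) + 1L]] <- data.frame(
          sample_id = sample_id, batch_id = rep(batch_id, each = spb),
          species = sp, analyte_id = aid, value = NA_real_,
          censored = TRUE, stringsAsFactors = FALSE)
        next
      }
      m <- scen$target_mean[i]
      cv <- scen$target_cv[i] / 100
      cv_b <- spec$between_batch_cv_ratio * cv
      cv_w <- sqrt((1 + cv^2) / (1 + cv_b^2) - 1)
      sig_b <- sqrt(log1p(cv_b^2))
      u <- lam * z_batch + sqrt(1 - lam^2) * stats::rnorm(nb)
      bmean <- m * exp(sig_b * u - sig_b^2 / 2)
      vals <- unlist(lapply(seq_len(nb), function(b) {
        if (spec$family == "lognormal") {
          sig_w <- sqrt(log1p(cv_w^2))
          bmean[b] * exp(sig_w * stats::rnorm(spb) - sig_w^2 / 2)
        } else {
          par <- calibrate_truncnorm(bmean[b], bmean[b] * cv_w)
          rtruncnorm0(spb, par[["mu"]], par[["sig"]])
        }
      }))
      cens <- if (apply_censoring) vals < lod else rep(FALSE, length(vals))
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        sample_id = sample_id, batch_id = rep(batch_id, each = spb),
        species = sp, analyte_id = aid,
        value = ifelse(cens, NA_real_, vals), censored = cens,
        stringsAsFactors = FALSE)
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        species = sp, batch_id = batch_id, analyte_id = aid,
        batch_mean = bmean, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  batch_meta <- do.call(rbind, bm_list)
  rownames(batch_meta) <- NULL
  ms <- measurement_set(records, panel = panel,
                        species_meta = spec$species_meta,
                        batch_meta = batch_meta)
  truth <- list(spec = spec, seed = seed,
                batch_latents = if (length(truth_list))
                  do.call(rbind, truth_list) else NULL,
                batch_meta = batch_meta)
  list(measurements = ms, truth = truth)
}

#' Write the sidecar truth file of a simulation
#'
#' Serializes the recipe (scenarios, seed, family, dispersion split) to
#' a key-value YAML file next to the measurement CSV, keeping the
#' generating truth out of the measurement table itself.
#'
#' @param truth the `truth` element returned by
#'   [simulate_measurements()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  spec <- truth$spec
  yaml::write_yaml(list(
    seed = truth$seed,
    family = spec$family,
    samples_per_batch = spec$samples_per_batch,
    between_batch_cv_ratio = spec$between_batch_cv_ratio,
    composition_correlation = spec$composition_correlation,
    scenarios = spec$scenarios), path)
  invisible(path)
}
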