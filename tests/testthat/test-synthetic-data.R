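test_that("identical seeds reproduce the simulation exactly; different seeds do not", {
  spec <- simulation_spec(table_scenarios(include_pcb = FALSE), seed = 4)
  a <- simulate_measurements(spec)
  b <- simulate_measurements(spec)
  expect_identical(a$measurements$records, b$measurements$records)
  expect_identical(a$truth$batch_latents, b$truth$batch_latents)
  c <- simulate_measurements(spec, seed = 5)
  expect_false(identical(a$measurements$records, c$measurements$records))
})

test_that("zero dispersion collapses every draw onto the target mean", {
  sc <- data.frame(species = "pollock", analyte_id = "dieldrin",
                   target_mean = 0.1336, target_cv = 0, censored = FALSE)
  meta <- fixture_composition()
  sim <- simulate_measurements(
    simulation_spec(sc, species_meta = meta[meta$species == "pollock", ]),
    seed = 8)
  expect_true(all(sim$measurements$records$value == 0.1336))
  expect_false(any(sim$measurements$records$censored))
})

test_that("the realized censored fraction matches the closed-form lognormal mass below LOD", {
  # scenario engineered for ~40% mass below the 0.01 ng/g LOD
  target_cv <- 60
  sig_t <- sqrt(log1p((target_cv / 100)^2))
  meanlog_target <- log(0.01) - qnorm(0.40) * sig_t
  m <- exp(meanlog_target + sig_t^2 / 2)
  sc <- data.frame(species = "panga", analyte_id = "aHCH",
                   target_mean = m, target_cv = target_cv, censored = FALSE)
  meta <- fixture_composition()
  meta <- meta[meta$species == "panga", , drop = FALSE]
  meta$n_batches <- 500
  sim <- simulate_measurements(simulation_spec(sc, species_meta = meta),
                               seed = 6)
  rec <- sim$measurements$records
  n <- nrow(rec)
  expect_identical(n, 5000L)
  p_expected <- plnorm(0.01, log(m) - sig_t^2 / 2, sig_t)
  p_real <- mean(rec$censored)
  half_width <- qnorm(0.995) * sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(p_real - p_expected), half_width + 0.01)
})

test_that("wholly-censored scenarios emit only censored records", {
  sc <- data.frame(species = "pollock",
                   analyte_id = c("dHCH", "aHCH"),
                   target_mean = c(NA, 0.2766),
                   target_cv = c(NA, 8.42),
                   censored = c(TRUE, FALSE), stringsAsFactors = FALSE)
  meta <- fixture_composition()
  sim <- simulate_measurements(
    simulation_spec(sc, species_meta = meta[meta$species == "pollock", ]),
    seed = 3)
  rec <- sim$measurements$records
  expect_true(all(rec$censored[rec$analyte_id == "dHCH"]))
  expect_true(all(is.na(rec$value[rec$analyte_id == "dHCH"])))
})

test_that("the truncated-normal family is calibrated to the target moments", {
  sc <- data.frame(species = "pacific_cod", analyte_id = "dieldrin",
                   target_mean = 0.2986, target_cv = 20.29,
                   censored = FALSE)
  meta <- fixture_composition()
  meta <- meta[meta$species == "pacific_cod", , drop = FALSE]
  meta$n_batches <- 400
  sim <- simulate_measurements(
    simulation_spec(sc, species_meta = meta, family = "truncated_normal"),
    seed = 12, apply_censoring = FALSE)
  x <- sim$measurements$records$value
  expect_true(all(x > 0))
  expect_equal(mean(x), 0.2986, tolerance = 0.03)
  expect_equal(100 * sd(x) / mean(x), 20.29, tolerance = 0.1)

  # CV >= 100% is outside the reach of a truncated normal
  sc$target_cv <- 150
  expect_error(simulation_spec(sc, species_meta = meta,
                               family = "truncated_normal"),
               "lognormal")
})

test_that("impossible recipes are rejected up front", {
  meta <- fixture_composition()
  sc <- data.frame(species = "panga", analyte_id = "aHCH",
                   target_mean = 0, target_cv = 50, censored = FALSE)
  expect_error(simulation_spec(sc, species_meta = meta), "impossible")
  sc2 <- data.frame(species = "atlantis_cod", analyte_id = "aHCH",
                    target_mean = 0.1, target_cv = 10, censored = FALSE)
  expect_error(simulation_spec(sc2, species_meta = meta), "species_meta")
})

test_that("the published-table fixture encodes the printed values and study structure", {
  ms <- paper_fixture()
  rec <- ms$records
  expect_equal(rec$value[rec$species == "nile_tilapia" &
                           rec$analyte_id == "aHCH"], 0.5069)
  expect_true(rec$censored[rec$species == "pacific_cod" &
                             rec$analyte_id == "pp_DDT"])
  expect_length(unique(rec$species), 5L)
  expect_identical(sum(ms$species_meta$n_samples), 790L)
  expect_identical(sum(ms$species_meta$n_batches), 79L)
  expect_identical(nrow(validate_measurement_set(ms)), 0L)
})

test_that("the truth sidecar stores the recipe without leaking into the CSV", {
  sc <- data.frame(species = "panga", analyte_id = "aHCH",
                   target_mean = 0.4529, target_cv = 36.09,
                   censored = FALSE)
  meta <- fixture_composition()
  sim <- simulate_measurements(
    simulation_spec(sc, species_meta = meta[meta$species == "panga", ],
                    seed = 77))
  truth_path <- withr::local_tempfile(fileext = ".yaml")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_simulation_truth(sim$truth, truth_path)
  write_measurements(sim$measurements, csv_path)
  truth <- yaml::read_yaml(truth_path)
  expect_equal(truth$seed, 77)
  expect_equal(truth$family, "lognormal")
  expect_false(any(grepl("target_mean", readLines(csv_path))))
})
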