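test_that("summary statistics use the sample SD and flag undefined CVs", {
  ms <- tiny_ms(make_records("panga", "aHCH", c(1, 2, 3)))
  sm <- summarize_measurements(ms)
  expect_equal(sm$mean, 2)
  expect_equal(sm$sd, 1)
  expect_equal(sm$median, 2)
  expect_equal(sm$cv, 50)

  const <- summarize_measurements(
    tiny_ms(make_records("panga", "aHCH", c(0.5, 0.5, 0.5))))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)

  cens <- summarize_measurements(
    tiny_ms(make_records("panga", "aHCH", c(NA_real_, NA_real_))))
  expect_equal(cens$mean, 0)
  expect_true(cens$cv_undefined)
  expect_true(is.na(cens$cv))

  expect_error(summarize_measurements(ms, species = "pollock"),
               "no records")
})

test_that("coefficient of variation matches hand arithmetic at reporting precision", {
  expect_equal(coefficient_of_variation(0.5069, 0.1562),
               round(100 * 0.1562 / 0.5069, 2))
  expect_equal(coefficient_of_variation(1, 0), 0)
  # recomputed from printed mean/SD: 12.80 (the table prints 12.81 from
  # unrounded intermediates; the recomputed value is reported)
  expect_equal(coefficient_of_variation(0.1055, 0.0135), 12.80)
  expect_error(coefficient_of_variation(0, 0.1), "> 0")
})

test_that("CV is invariant under positive rescaling of the data", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rlnorm(10)
    k <- runif(1, 0.1, 50)
    cv1 <- coefficient_of_variation(mean(x), sd(x), digits = NULL)
    cv2 <- coefficient_of_variation(mean(k * x), sd(k * x), digits = NULL)
    expect_equal(cv1, cv2)
  }
})

test_that("metabolite shares reproduce the published endosulfan-sulfate dominance", {
  tilapia <- c(endosulfan_a = 0.0285, endosulfan_b = 0.0293,
               endosulfan_sulfate = 0.1073)
  expect_equal(round(metabolite_share(tilapia, "endosulfan_sulfate")), 65)
  sole <- c(endosulfan_a = 0.0205, endosulfan_b = 0,
            endosulfan_sulfate = 0.0740)
  expect_equal(round(metabolite_share(sole, "endosulfan_sulfate")), 78)
  expect_equal(metabolite_share(c(a = 0, b = 0, s = 0.07), "s"), 100)
  expect_error(metabolite_share(c(a = 0, b = 0), "a"), "zero")
})

test_that("metabolite shares over a component set always sum to 100", {
  set.seed(31)
  for (rep in 1:20) {
    comp <- setNames(runif(4), paste0("c", 1:4))
    total <- sum(vapply(names(comp),
                        function(nm) metabolite_share(comp, nm),
                        numeric(1)))
    expect_equal(total, 100)
  }
})

test_that("pearson correlation handles limiting and hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(1:4, 1:5), "lengths differ")
})

test_that("pearson r is invariant under positive-slope affine transforms", {
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    expect_equal(pearson_correlation(a * x + b, y)$r,
                 pearson_correlation(x, y)$r)
  }
})

test_that("summaries recover the generating mean within 3 SE in almost all repetitions", {
  # replication as in the emulated study: 10 samples per batch
  sc <- data.frame(species = "nile_tilapia", analyte_id = "dieldrin",
                   target_mean = 0.1356, target_cv = 18.64,
                   censored = FALSE, stringsAsFactors = FALSE)
  meta <- fixture_composition()
  meta <- meta[meta$species == "nile_tilapia", , drop = FALSE]
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    sim <- simulate_measurements(simulation_spec(sc, species_meta = meta),
                                 seed = 5000 + s)
    rec <- sim$measurements$records
    rec$subst <- substitute_censored(rec, sim$measurements$panel,
                                     censoring_policy())
    bm <- tapply(rec$subst, rec$batch_id, mean)
    se <- sd(bm) / sqrt(length(bm))
    if (abs(mean(bm) - sc$target_mean) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.99)
})

test_that("composition correlations are exercisable on simulated batches", {
  sc <- data.frame(species = "panga", analyte_id = "bHCH",
                   target_mean = 0.0907, target_cv = 80.29,
                   censored = FALSE, stringsAsFactors = FALSE)
  meta <- fixture_composition()
  meta <- meta[meta$species == "panga", , drop = FALSE]
  meta$n_batches <- 400
  sim <- simulate_measurements(simulation_spec(sc, species_meta = meta),
                               seed = 9)
  cc <- correlate_with_composition(sim$measurements)
  expect_setequal(cc$covariate, c("dry_mass", "fat"))
  # configured latent correlation 0.4; Pearson on the skewed level scale
  # is attenuated but clearly positive
  expect_true(all(cc$r > 0.15))
  expect_true(all(abs(cc$r) <= 1))
})
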