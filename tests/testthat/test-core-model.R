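test_that("censored substitution follows the policy and leaves observed values alone", {
  panel <- default_panel()
  rec <- make_records("nile_tilapia", "aHCH", c(0.5069, NA, 0.12))
  expect_equal(substitute_censored(rec, panel, censoring_policy("zero")),
               c(0.5069, 0, 0.12))
  expect_equal(substitute_censored(rec, panel, censoring_policy("half_lod")),
               c(0.5069, 0.005, 0.12))
  expect_equal(substitute_censored(rec, panel, censoring_policy("lod")),
               c(0.5069, 0.01, 0.12))
})

test_that("substitution is monotone in the policy for any analyte", {
  panel <- default_panel()
  set.seed(11)
  for (rep in 1:25) {
    aid <- sample(panel$analyte_id, 4)
    rec <- data.frame(
      sample_id = paste0("S", 1:4), batch_id = "B01", species = "panga",
      analyte_id = aid,
      value = ifelse(runif(4) < 0.5, NA, runif(4)),
      stringsAsFactors = FALSE)
    rec$censored <- is.na(rec$value)
    z <- substitute_censored(rec, panel, censoring_policy("zero"))
    h <- substitute_censored(rec, panel, censoring_policy("half_lod"))
    l <- substitute_censored(rec, panel, censoring_policy("lod"))
    expect_true(all(z <= h & h <= l))
  }
})

test_that("substitution rejects unknown analytes and negative observed values", {
  panel <- default_panel()
  bad_id <- make_records("panga", "notAnAnalyte", 0.1)
  expect_error(substitute_censored(bad_id, panel, censoring_policy()),
               "unknown analyte")
  neg <- make_records("panga", "aHCH", -0.1)
  expect_error(substitute_censored(neg, panel, censoring_policy()),
               ">= 0")
})

test_that("validation reports violations as data and passes the clean fixture", {
  expect_identical(nrow(validate_measurement_set(paper_fixture())), 0L)

  rec <- make_records("panga", "aHCH", c(0.1, 0.2))
  rec$value[2] <- -1
  v <- validate_measurement_set(tiny_ms(rec))
  expect_identical(v$rule, "invalid_value")
  expect_identical(v$sample_id, rec$sample_id[2])

  rec2 <- make_records("panga", c("aHCH", "ghost"), c(0.1, 0.2))
  v2 <- validate_measurement_set(tiny_ms(rec2))
  expect_identical(v2$rule, "unresolved_analyte")
  expect_identical(v2$analyte_id, "ghost")

  rec3 <- rbind(make_records("panga", "aHCH", 0.1),
                make_records("panga", "aHCH", 0.2))
  v3 <- validate_measurement_set(tiny_ms(rec3))
  expect_true("duplicate_key" %in% v3$rule)
})

test_that("measurement CSV round-trips field-for-field including censoring markers", {
  sim <- simulate_measurements(
    simulation_spec(table_scenarios(include_pcb = FALSE), seed = 3))
  ms <- sim$measurements
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ms, path)
  back <- read_measurements(path, species_meta = ms$species_meta)
  expect_equal(back$records, ms$records)
  expect_gt(sum(back$records$censored), 0)
})

test_that("malformed measurement CSV rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,batch_id,species,analyte_id,value",
               "S1,B1,panga,aHCH,0.2",
               "S2,B1,panga,aHCH,not-a-number"), path)
  expect_error(read_measurements(path), "line\\(s\\) 2")
})

test_that("reference config round-trips through YAML and validates its invariants", {
  ref <- default_reference_tables()
  expect_true(all(ref$tef >= 0 & ref$tef <= 1))
  expect_true(all(ref$rfd > 0))
  expect_lt(ref$twi_new, ref$twi_old)
  expect_setequal(names(ref$tef), dl_pcb_ids())
  expect_setequal(names(ref$rfd), ocp_ids())

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(ref$config, path)
  again <- read_reference_config(path)
  expect_equal(again$tef, ref$tef)
  expect_equal(again$rfd, ref$rfd)
  expect_equal(again$adc_hq, ref$adc_hq)

  broken <- ref$config
  broken$intake$bw <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, path2)
  expect_error(read_reference_config(path2), "bw")
})

test_that("panel LODs never exceed LOQs and families route analytes correctly", {
  panel <- default_panel()
  expect_true(all(panel$lod <= panel$loq))
  expect_length(dl_pcb_ids(panel), 12L)
  expect_length(ocp_ids(panel), 15L)
  expect_false(any(dl_pcb_ids(panel) %in% ocp_ids(panel)))
  # config override flows into the panel
  cfg <- default_reference_tables()$config
  cfg$lod$aHCH <- 0.002
  p2 <- default_panel(cfg)
  expect_equal(p2$lod[p2$analyte_id == "aHCH"], 0.002)
})
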