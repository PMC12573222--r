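test_that("default spec encodes the study conditions", {
  spec <- default_population_spec()
  expect_equal(sum(spec$strata$n), 706)
  expect_equal(spec$strata$n, c(189L, 230L, 137L, 150L))
  expect_equal(spec$strata$stratum, c("6-11", "12-18", "19-64", "65+"))
  expect_equal(spec$sex_ratio, 0.5)
  expect_equal(spec$analytes$MP$geometric_mean, 17.54)
  expect_equal(
    vapply(spec$analytes, `[[`, 0, "geometric_mean"),
    c(MP = 17.54, EP = 0.97, PP = 1.60, BPA = 1.19)
  )
  for (a in spec$analytes) {
    expect_lt(a$lod, a$loq)
    expect_gt(a$geometric_sd, 1)
  }
  expect_setequal(names(spec$food_groups), food_group_ids())
  # all couplings off by default
  expect_true(all(spec$diet_effects == 0))
})

test_that("spec constructors reject invalid inputs", {
  expect_error(analyte_spec("MP", lod = 0.11, loq = 0.03,
                            geometric_mean = 1, geometric_sd = 2), "lod")
  expect_error(analyte_spec("MP", 0.03, 0.11, geometric_mean = 1,
                            geometric_sd = 0.9), "geometric_sd")
  expect_error(food_group_spec("oil", consumption_probability = 1.2,
                               intake_log_mean = 0, intake_log_sd = 1),
               "probability")
  spec <- default_population_spec()
  bad_strata <- spec$strata
  bad_strata$n[2] <- 0L
  expect_error(population_spec(bad_strata, spec$analytes, spec$food_groups),
               "sizes")
})

test_that("population generation is seeded and respects stratum structure", {
  spec <- default_population_spec()
  pop1 <- generate_population(spec, seed = 1)
  pop2 <- generate_population(spec, seed = 1)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 706)
  pop3 <- generate_population(spec, seed = 2)
  expect_false(identical(pop1, pop3))
  expect_true(all(pop1$body_weight > 0 & pop1$height > 0))
  by_stratum <- split(pop1$age, pop1$stratum)
  expect_true(all(by_stratum[["6-11"]] >= 6 & by_stratum[["6-11"]] < 12))
  expect_true(all(by_stratum[["65+"]] >= 65))
  # body weight and height positively correlated within stratum
  adults <- pop1[pop1$stratum == "19-64", ]
  expect_gt(cor(adults$body_weight, adults$height), 0.2)
})

test_that("intakes reproduce the published cooked-weight scales", {
  spec <- default_population_spec()
  pop <- generate_population(spec, seed = 3)
  intk <- generate_intakes(pop, spec, seed = 3)
  kids <- intk[intk$stratum == "6-11", ]
  # zero-inflated groups: median poultry intake in children is zero
  expect_equal(median(kids$poultry), 0)
  # grain median within 20% of the published 314.45 g
  expect_lt(abs(median(kids$grain) / 314.45 - 1), 0.20)
  expect_true(all(as.matrix(intk[food_group_ids()]) >= 0))
})

test_that("degenerate intake distributions collapse to a point mass", {
  spec <- default_population_spec()
  spec$food_groups$oil <- food_group_spec(
    "oil", consumption_probability = 1,
    intake_log_mean = log(15), intake_log_sd = 0
  )
  pop <- generate_population(spec, seed = 1)
  intk <- generate_intakes(pop, spec, seed = 1)
  expect_true(all(intk$oil == 15))
})

test_that("biomarkers are censored consistently and reproducibly", {
  spec <- scaled_spec(c(80L, 80L, 80L, 80L))
  pop <- generate_population(spec, seed = 5)
  intk <- generate_intakes(pop, spec, seed = 5)
  bio1 <- generate_biomarkers(pop, spec, intk, seed = 5)
  bio2 <- generate_biomarkers(pop, spec, intk, seed = 5)
  expect_identical(bio1, bio2)
  expect_identical(bio1$censored, bio1$raw_concentration < bio1$lod)
  expect_true(all(bio1$raw_concentration > 0))
  expect_true(all(bio1$creatinine > 0))
  shuffled <- intk[rev(seq_len(nrow(intk))), ]
  expect_identical(bio1, generate_biomarkers(pop, spec, shuffled, seed = 5))
  expect_error(
    generate_biomarkers(pop, spec, intk[-1, ], seed = 5),
    "identifiers"
  )
})

test_that("the default population hits the published MP detection rate", {
  spec <- default_population_spec()
  study <- simulate_study(spec, seed = 7)
  mp <- study$biomarkers[study$biomarkers$analyte_id == "MP", ]
  expect_lt(abs(detection_rate(mp) - 0.9830), 0.03)
})

test_that("simulated geometric means recover the spec at large n", {
  # flat stratum ratios isolate the marginal lognormal
  spec <- scaled_spec(rep(25000L, 4))
  spec$analytes$MP$stratum_gm_ratio[] <- 1
  pop <- generate_population(spec, seed = 11)
  intk <- generate_intakes(pop, spec, seed = 11)
  bio <- generate_biomarkers(pop, spec, intk, seed = 11)
  mp <- bio[bio$analyte_id == "MP", ]
  gm <- exp(mean(log(mp$raw_concentration / mp$creatinine)))
  expect_lt(abs(gm / spec$analytes$MP$geometric_mean - 1), 0.02)
})

test_that("with zero couplings biomarkers are independent of intake", {
  spec <- scaled_spec(rep(500L, 4))
  study <- simulate_study(spec, seed = 13)
  p <- process_biomarkers(study$biomarkers)
  kids <- study$participants$subject_id[study$participants$stratum == "19-64"]
  d <- merge(
    p[p$analyte_id == "EP" & p$subject_id %in% kids,
      c("subject_id", "adjusted")],
    study$intakes[, c("subject_id", "snack")]
  )
  expect_lt(abs(cor(d$adjusted, d$snack, method = "spearman")), 0.1)
})

test_that("an injected coupling shifts the biomarker as specified", {
  spec <- scaled_spec(rep(2000L, 4))
  spec$analytes$EP$stratum_gm_ratio[] <- 1
  beta <- 0.05
  spec2 <- inject_effect(spec, "EP", "snack", beta)
  pop <- generate_population(spec, seed = 17)
  intk <- generate_intakes(pop, spec, seed = 17)
  bio0 <- generate_biomarkers(pop, spec, intk, seed = 17)
  bio1 <- generate_biomarkers(pop, spec2, intk, seed = 17)
  ep0 <- log(bio0$raw_concentration[bio0$analyte_id == "EP"])
  ep1 <- log(bio1$raw_concentration[bio1$analyte_id == "EP"])
  x <- intk$snack[match(bio0$subject_id[bio0$analyte_id == "EP"],
                        intk$subject_id)]
  # same seed, same noise: the log shift is beta * intake / 100 exactly
  # (up to exp/log round-trip error)
  expect_lt(max(abs((ep1 - ep0) - beta * x / 100)), 1e-10)
})

test_that("study tables round-trip through CSV and YAML", {
  spec <- scaled_spec(c(12L, 12L, 12L, 12L))
  study <- simulate_study(spec, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_study_tables(study, dir, spec = spec)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["participants"]], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(study$participants))
  spec_back <- yaml::read_yaml(paths[["spec"]])
  expect_equal(spec_back$analytes$MP$geometric_mean, 17.54)
})
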