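# Minimal hand-built study for association tests: one stratum of n
# subjects, the target intake columns controlled by the caller, the rest
# filled with independent positive noise.
assoc_fixture <- function(n, intake_values, adjusted, sex = NULL, seed = 404) {
  ids <- sprintf("A%03d", seq_len(n))
  intakes <- tibble::tibble(subject_id = ids)
  filler <- withr::with_seed(seed, {
    lapply(food_group_ids(), function(g) runif(n, 1, 50))
  })
  names(filler) <- food_group_ids()
  for (g in food_group_ids()) {
    intakes[[g]] <- if (g %in% names(intake_values)) intake_values[[g]] else filler[[g]]
  }
  list(
    processed = tibble::tibble(
      subject_id = ids, analyte_id = "EP", adjusted = adjusted
    ),
    intakes = intakes,
    participants = tibble::tibble(
      subject_id = ids,
      sex = if (is.null(sex)) rep(c("male", "female"), length.out = n) else sex
    )
  )
}

test_that("Spearman screening matches the hand-ranked formula", {
  x <- c(1, 2, 3, 4, 5)
  fx <- assoc_fixture(5, list(oil = x), adjusted = x * 2)
  # perfect monotone association
  out <- spearman_matrix(fx$processed, fx$intakes, min_pairs = 5)
  expect_equal(out$rho[out$food_group == "oil"], 1)
  fx2 <- assoc_fixture(5, list(oil = x), adjusted = rev(x))
  out2 <- spearman_matrix(fx2$processed, fx2$intakes, min_pairs = 5)
  expect_equal(out2$rho[out2$food_group == "oil"], -1)
  # hand-ranked: d = (1,1,1,1,0), rho = 1 - 6*4/120 = 0.8
  fx3 <- assoc_fixture(5, list(oil = x), adjusted = c(2, 1, 4, 3, 5))
  out3 <- spearman_matrix(fx3$processed, fx3$intakes, min_pairs = 5)
  expect_equal(out3$rho[out3$food_group == "oil"], 0.8)
})

test_that("Spearman is invariant to strictly monotone transforms", {
  withr::with_seed(15, {
    x <- rlnorm(60, 3, 1)
    y <- rlnorm(60, 0, 1)
    fx <- assoc_fixture(60, list(snack = x), adjusted = y)
    fx_t <- assoc_fixture(60, list(snack = exp(x / 50)), adjusted = y^3)
    r1 <- spearman_matrix(fx$processed, fx$intakes)
    r2 <- spearman_matrix(fx_t$processed, fx_t$intakes)
    expect_equal(r1$rho[r1$food_group == "snack"],
                 r2$rho[r2$food_group == "snack"], tolerance = 1e-12)
  })
})

test_that("Spearman screening rejects degenerate cells", {
  fx <- assoc_fixture(5, list(oil = 1:5), adjusted = 1:5)
  expect_error(spearman_matrix(fx$processed, fx$intakes, min_pairs = 20),
               "pairs")
  fx$processed$adjusted <- rep(1, 5)
  expect_error(spearman_matrix(fx$processed, fx$intakes, min_pairs = 5),
               "constant")
})

test_that("mutually adjusted regression recovers a planted coefficient", {
  withr::with_seed(22, {
    n <- 300
    oil <- rlnorm(n, 3, 0.6)
    grain <- rlnorm(n, 5, 0.4)
    y <- 1 + 0.2 * oil + rnorm(n, 0, 0.5)
    fx <- assoc_fixture(n, list(oil = oil, grain = grain), adjusted = y)
    fit <- mlr_food_groups(fx$processed, fx$intakes, fx$participants,
                           "EP", c("oil", "grain"))
    b <- fit$coefficients
    est <- b$estimate[b$term == "oil"]
    expect_gt(est, 0.15)
    expect_lt(est, 0.25)
    expect_lt(b$p_value[b$term == "oil"], 0.001)
    expect_true(b$conf_low[b$term == "oil"] <= est &
                  est <= b$conf_high[b$term == "oil"])
    expect_equal(fit$r, sqrt(fit$r_squared))
  })
})

test_that("null regression coefficients cover zero at the nominal rate", {
  covered <- withr::with_seed(23, {
    vapply(1:100, function(i) {
      n <- 120
      oil <- rlnorm(n, 3, 0.6)
      y <- rnorm(n)
      fx <- assoc_fixture(n, list(oil = oil), adjusted = y)
      b <- mlr_food_groups(fx$processed, fx$intakes, fx$participants,
                           "EP", "oil")$coefficients
      b$conf_low[b$term == "oil"] <= 0 && 0 <= b$conf_high[b$term == "oil"]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.90)
})

test_that("duplicated food-group columns are reported as rank deficiency", {
  fx <- assoc_fixture(50, list(oil = rlnorm(50)), adjusted = rnorm(50))
  fx$intakes$oil2 <- fx$intakes$oil
  expect_error(
    mlr_food_groups(fx$processed, fx$intakes, fx$participants,
                    "EP", c("oil", "oil2")),
    "rank-deficient.*oil2"
  )
})

test_that("g-computation is seeded and near-null without a planted effect", {
  spec <- scaled_spec(rep(100L, 4))
  study <- simulate_study(spec, seed = 31)
  p <- process_biomarkers(study$biomarkers)
  run <- function(seed) {
    suppressWarnings(gcomputation_effect(
      p, study$intakes, study$participants, "EP", "snack",
      n_boot = 300, seed = seed
    ))
  }
  e1 <- run(7)
  e2 <- run(7)
  expect_identical(e1, e2)
  expect_false(identical(e1$conf_low, run(8)$conf_low))
  expect_true(e1$conf_low <= 0 && 0 <= e1$conf_high)
  expect_gt(e1$p_value, 0.05)
})

test_that("g-computation recovers a planted positive diet effect", {
  spec <- recovery_spec()
  beta <- calibrate_beta(spec, "MP", "vegetable", 20)
  spec2 <- inject_effect(spec, "MP", "vegetable", beta)
  study <- simulate_study(spec2, seed = 33)
  p <- process_biomarkers(study$biomarkers)
  truth <- gcomp_truth(spec2, study$participants, study$intakes,
                       "MP", "vegetable")
  est <- suppressWarnings(gcomputation_effect(
    p, study$intakes, study$participants, "MP", "vegetable",
    n_boot = 400, seed = 9
  ))
  expect_gt(truth, 10) # the planted contrast is a substantial increase
  expect_true(est$conf_low <= truth && truth <= est$conf_high)
  expect_lt(est$p_value, 0.05)
})

test_that("with an identity outcome model g-computation degenerates to the
           marginal mean difference", {
  withr::with_seed(41, {
    n <- 80
    x <- rep(c(0, 100), each = n / 2)
    y <- 5 + 2 * (x == 100) + rnorm(n, 0, 0.3)
    fx <- assoc_fixture(n, list(poultry = x), adjusted = y)
    est <- suppressWarnings(gcomputation_effect(
      fx$processed, fx$intakes, fx$participants, "EP", "poultry",
      covariate_groups = "poultry", contrast = c(0, 100),
      outcome_transform = "identity", n_boot = 200, seed = 1
    ))
    marginal <- mean(y[x == 100]) - mean(y[x == 0])
    expect_equal(est$estimate, marginal, tolerance = 1e-10)
  })
})

test_that("counterfactuals outside the observed support raise an
           extrapolation warning", {
  withr::with_seed(43, {
    n <- 60
    grain <- rlnorm(n, 5, 0.3) # always consumed: zero is out of support
    fx <- assoc_fixture(n, list(grain = grain), adjusted = rlnorm(n))
    expect_warning(
      gcomputation_effect(fx$processed, fx$intakes, fx$participants,
                          "EP", "grain", n_boot = 200, seed = 1),
      class = "edcrisk_extrapolation"
    )
  })
})

test_that("effect weights are signed proportions of the absolute total", {
  expect_equal(effect_weights(c(2, -1, 3)), c(1 / 3, -1 / 6, 1 / 2))
  expect_equal(effect_weights(5), 1)
  expect_equal(effect_weights(-5), -1)
  expect_equal(effect_weights(c(1, -1)), c(0.5, -0.5))
  expect_warning(w <- effect_weights(c(0, 0)), "undefined")
  expect_true(all(is.na(w)))
  withr::with_seed(44, {
    for (i in 1:10) {
      e <- rnorm(12)
      expect_equal(sum(abs(effect_weights(e))), 1)
      expect_equal(sign(effect_weights(e)), sign(e))
    }
  })
})

test_that("the scan attaches weights across food groups", {
  spec <- scaled_spec(rep(60L, 4))
  study <- simulate_study(spec, seed = 51)
  p <- process_biomarkers(study$biomarkers)
  out <- suppressWarnings(gcomputation_scan(
    p, study$intakes, study$participants, "BPA",
    food_groups = c("snack", "fruit", "oil"), n_boot = 200, seed = 3
  ))
  expect_equal(nrow(out), 3)
  expect_equal(sum(abs(out$weight)), 1)
})
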