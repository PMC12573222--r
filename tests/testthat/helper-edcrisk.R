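# Shared fixtures: all synthetic, built in code.

# Default spec with per-stratum sample sizes overridden (for fast tests).
scaled_spec <- function(n = c(40L, 40L, 40L, 40L)) {
  spec <- default_population_spec()
  spec$strata$n <- as.integer(rep_len(n, 4))
  spec
}

# Spec with a single nonzero diet->biomarker coupling injected.
inject_effect <- function(spec, analyte, food_group, beta) {
  spec$diet_effects[food_group, analyte] <- beta
  spec
}

# Closed-form population-average percent change for the observed-vs-zero
# contrast of `food_group` on `analyte`, given the generator's log-linear
# structure: subjects are weighted by their mean outcome under zero target
# intake (stratum GM x other injected effects), and the target multiplies
# it by exp(beta * intake / 100).
gcomp_truth <- function(spec, participants, intakes, analyte, food_group) {
  intakes <- intakes[match(participants$subject_id, intakes$subject_id), ]
  a <- spec$analytes[[analyte]]
  s_idx <- match(participants$stratum, age_stratum_labels())
  beta <- spec$diet_effects[, analyte]
  x <- as.matrix(intakes[food_group_ids()]) / 100
  other <- setdiff(food_group_ids(), food_group)
  w <- a$stratum_gm_ratio[s_idx] * exp(drop(x[, other, drop = FALSE] %*% beta[other]))
  r <- exp(beta[food_group] * x[, food_group])
  (sum(w * r) / sum(w) - 1) * 100
}

# Conditions for estimator-recovery studies: whole-population analyses need
# an age-homogeneous concentration scale (the outcome model adjusts for sex
# and diet, not age), and a moderate residual dispersion so a +/-20%
# contrast is identifiable at survey size.
recovery_spec <- function(analyte = "MP", residual_gsd = 2.5) {
  sp <- default_population_spec()
  sp$analytes[[analyte]]$stratum_gm_ratio[] <- 1
  sp$residual_log_sd[[analyte]] <- log(residual_gsd)
  sp
}

# Calibrate the log-linear coefficient of `food_group` on `analyte` so the
# observed-vs-zero contrast equals `target_pct` percent under the spec's
# intake distribution (computed on one large reference population).
calibrate_beta <- function(spec, analyte, food_group, target_pct,
                           n_ref = 1000L, seed = 2024L) {
  big <- spec
  big$strata$n <- rep(n_ref, 4)
  pop <- generate_population(big, seed)
  intk <- generate_intakes(pop, big, seed + 1L)
  f <- function(b) {
    sp <- inject_effect(spec, analyte, food_group, b)
    gcomp_truth(sp, pop, intk, analyte, food_group) - target_pct
  }
  stats::uniroot(f, c(-2, 2), tol = 1e-8)$root
}
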