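# Assemble the analysis frame for one analyte: creatinine-adjusted
# concentration, sex, and the requested intake columns, one row per
# subject.
association_frame <- function(processed, intakes, participants, analyte,
                              groups = FOOD_GROUPS) {
  y <- processed %>%
    filter(.data$analyte_id == analyte) %>%
    select("subject_id", "adjusted")
  if (nrow(y) == 0) abort(paste0("no measurements for analyte ", analyte, "."))
  y %>%
    left_join(select(intakes, all_of(c("subject_id", groups))),
              by = "subject_id") %>%
    left_join(select(participants, all_of(c("subject_id", "sex"))),
              by = "subject_id") %>%
    filter(complete.cases(.))
}

#' Spearman correlation screen of diet against biomarkers
#'
#' Rank correlation (with tie handling) of each analyte's
#' creatinine-adjusted concentration against each food group's daily
#' intake, with two-sided p-values.  Subset the inputs to one age stratum
#' to obtain stratified screens.
#'
#' @param processed Output of [process_biomarkers()].
#' @param intakes Wide intake table ([generate_intakes()] layout).
#' @param min_pairs Minimum complete pairs per cell, default 10.
#' @return A tibble: `analyte_id`, `food_group`, `n`, `rho`, `p_value`.
#' @export
spearman_matrix <- function(processed, intakes, min_pairs = 10) {
  combos <- tidyr::expand_grid(
    analyte_id = intersect(ANALYTES, unique(processed$analyte_id)),
    food_group = FOOD_GROUPS
  )
  purrr::pmap_dfr(combos, function(analyte_id, food_group) {
    d <- processed %>%
      filter(.data$analyte_id == !!analyte_id) %>%
      select("subject_id", "adjusted") %>%
      left_join(select(intakes, all_of(c("subject_id", food_group))),
                by = "subject_id")
    x <- d[[food_group]]
    y <- d$adjusted
    ok <- complete.cases(x, y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < min_pairs) {
      abort(paste0("fewer than ", min_pairs, " complete pairs for ",
                   analyte_id, " x ", food_group, "."))
    }
    if (diff(range(x)) == 0 || diff(range(y)) == 0) {
      abort(paste0("constant column in ", analyte_id, " x ", food_group, "."))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(
      analyte_id = analyte_id, food_group = food_group, n = length(x),
      rho = unname(ct$estimate), p_value = ct$p.value
    )
  })
}

#' Food groups flagged by the Spearman screen
#'
#' @param screen Output of [spearman_matrix()].
#' @param alpha Significance level, default 0.05.
#' @return A named list (by analyte) of significant food groups.
#' @export
significant_food_groups <- function(screen, alpha = 0.05) {
  sig <- filter(screen, .data$p_value < alpha)
  lapply(split(sig$food_group, factor(sig$analyte_id, ANALYTES)), unique)
}

#' Mutually adjusted multiple linear regression
#'
#' Least-squares regression of an analyte's creatinine-adjusted
#' concentration (untransformed, ug/g-creatinine) on the selected food
#' groups entered jointly, adjusted for sex, with 95% confidence intervals
#' and p-values.  Intended for the food groups flagged by the Spearman
#' screen.
#'
#' @inheritParams spearman_matrix
#' @param participants Table with `subject_id` and `sex`.
#' @param analyte Analyte to model.
#' @param food_groups Food groups entered jointly (character vector).
#' @return A list: `coefficients` (tibble `term`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`), `r`, `r_squared`, `n`.
#' @export
mlr_food_groups <- function(processed, intakes, participants, analyte,
                            food_groups) {
  stopifnot(all(food_groups %in% names(intakes)))
  d <- association_frame(processed, intakes, participants, analyte,
                         groups = unique(food_groups))
  fml <- stats::reformulate(c("sex", food_groups), response = "adjusted")
  X <- model.matrix(fml, d)
  r <- qr(X)$rank
  if (r < ncol(X)) {
    fit0 <- lm.fit(X, d$adjusted)
    bad <- colnames(X)[is.na(fit0$coefficients)]
    abort(paste0("rank-deficient design; offending column(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  ci <- confint(fit)
  list(
    coefficients = tibble(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, 1],
      conf_low = ci[, 1], conf_high = ci[, 2],
      p_value = sm$coefficients[, 4]
    ),
    r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    n = nrow(d)
  )
}

# Counterfactual intake pair (b = reference, a = index) for the target
# group under a named or numeric contrast.
contrast_pair <- function(x, contrast, shift) {
  if (is.numeric(contrast)) {
    if (length(contrast) != 2) abort("numeric `contrast` must be length 2 (reference, index).")
    return(list(b = rep(contrast[1], length(x)), a = rep(contrast[2], length(x))))
  }
  switch(contrast,
    zero = list(b = rep(0, length(x)), a = x),
    iqr = {
      q <- quantile(x, c(0.25, 0.75), names = FALSE)
      list(b = rep(q[1], length(x)), a = rep(q[2], length(x)))
    },
    shift = list(b = x, a = x + shift)
  )
}

#' G-computation population-average effect of one food group
#'
#' Fits an outcome model of the (by default natural-log) creatinine-adjusted
#' concentration on all food groups plus sex, predicts every subject's
#' outcome under an index and a reference setting of the target group's
#' intake, and contrasts the back-transformed population means:
#' `percent_change = (mean_index / mean_reference - 1) * 100`.  The default
#' contrast compares observed intake (index) against zero intake of the
#' target group (reference); alternatives are an interquartile shift
#' (`"iqr"`, P75 vs P25 for everyone), an additive shift (`"shift"`,
#' observed + `shift` g/day vs observed), or an explicit numeric pair.
#' Inference is by nonparametric subject-level bootstrap: percentile
#' confidence interval and a p-value by interval inversion.  Deterministic
#' given `seed`.
#'
#' @inheritParams mlr_food_groups
#' @param target_group The food group whose effect is estimated.
#' @param covariate_groups Food groups entered as covariates; default all
#'   12 (the target's coefficient is mutually adjusted).
#' @param contrast `"zero"` (default), `"iqr"`, `"shift"`, or a numeric
#'   pair `c(reference, index)` in g/day.
#' @param shift Shift size in g/day for `contrast = "shift"`, default 100.
#' @param n_boot Bootstrap replicates, at least 200; default 1000.
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG.
#' @param outcome_transform `"log"` (default; effects as percent changes)
#'   or `"identity"` (effects as absolute mean differences).
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `analyte_id`, `food_group`, `contrast`,
#'   `estimate` (percent change, or mean difference for the identity
#'   transform), `conf_low`, `conf_high`, `p_value`, `n`, `n_boot`.
#' @export
gcomputation_effect <- function(processed, intakes, participants, analyte,
                                target_group,
                                covariate_groups = FOOD_GROUPS,
                                contrast = "zero", shift = 100,
                                n_boot = 1000, seed = NULL,
                                outcome_transform = c("log", "identity"),
                                conf_level = 0.95) {
  outcome_transform <- match.arg(outcome_transform)
  stopifnot(target_group %in% FOOD_GROUPS || target_group %in% names(intakes))
  if (n_boot < 200) abort("`n_boot` must be at least 200.")
  groups <- union(covariate_groups, target_group)
  d <- association_frame(processed, intakes, participants, analyte,
                         groups = groups)
  if (nrow(d) < 30) abort("g-computation requires at least 30 subjects.")
  y <- if (outcome_transform == "log") {
    if (any(d$adjusted <= 0)) abort("log outcome requires positive concentrations.")
    log(d$adjusted)
  } else {
    d$adjusted
  }
  # Intakes enter per 100 g/day for numerical balance.
  X <- cbind(
    `(Intercept)` = 1,
    sexmale = as.numeric(d$sex == "male"),
    as.matrix(d[groups]) / 100
  )
  # Constant covariate columns (e.g. a single-sex subset) carry no
  # information and would make the fit singular; drop all but the target.
  info <- vapply(seq_len(ncol(X)), function(j) {
    colnames(X)[j] %in% c("(Intercept)", target_group) ||
      diff(range(X[, j])) > 0
  }, logical(1))
  X <- X[, info, drop = FALSE]
  tcol <- which(colnames(X) == target_group)
  pair <- contrast_pair(d[[target_group]], contrast, shift)
  obs_range <- range(d[[target_group]])
  if (any(c(pair$a, pair$b) < obs_range[1] - 1e-9) ||
      any(c(pair$a, pair$b) > obs_range[2] + 1e-9)) {
    warn("counterfactual intake lies outside the observed support; the contrast extrapolates.",
         class = "edcrisk_extrapolation")
  }
  Xa <- X
  Xa[, tcol] <- pair$a / 100
  Xb <- X
  Xb[, tcol] <- pair$b / 100
  point <- function(idx) {
    fit <- lm.fit(X[idx, , drop = FALSE], y[idx])
    co <- fit$coefficients
    if (anyNA(co)) {
      return(NA_real_)
    }
    pa <- Xa[idx, , drop = FALSE] %*% co
    pb <- Xb[idx, , drop = FALSE] %*% co
    if (outcome_transform == "log") {
      (mean(exp(pa)) / mean(exp(pb)) - 1) * 100
    } else {
      mean(pa) - mean(pb)
    }
  }
  n <- nrow(X)
  estimate <- point(seq_len(n))
  boot <- with_seed_or_current(seed, {
    vapply(seq_len(n_boot), function(b) point(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  boot <- boot[!is.na(boot)]
  alpha <- 1 - conf_level
  ci <- quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min(
    (1 + sum(boot <= 0)) / (length(boot) + 1),
    (1 + sum(boot >= 0)) / (length(boot) + 1)
  )
  tibble(
    analyte_id = analyte, food_group = target_group,
    contrast = if (is.numeric(contrast)) paste(contrast, collapse = "->") else contrast,
    estimate = estimate, conf_low = ci[1], conf_high = ci[2],
    p_value = min(p, 1), n = n, n_boot = length(boot)
  )
}

#' G-computation effects of every food group on one analyte
#'
#' Runs [gcomputation_effect()] for each food group in turn (same outcome
#' model, mutually adjusted) and appends the signed effect weights.
#'
#' @inheritParams gcomputation_effect
#' @param food_groups Food groups to scan, default all 12.
#' @return A tibble of effects with a `weight` column from
#'   [effect_weights()].
#' @export
gcomputation_scan <- function(processed, intakes, participants, analyte,
                              food_groups = FOOD_GROUPS, contrast = "zero",
                              shift = 100, n_boot = 1000, seed = NULL) {
  effects <- purrr::map_dfr(seq_along(food_groups), function(i) {
    gcomputation_effect(
      processed, intakes, participants, analyte, food_groups[i],
      contrast = contrast, shift = shift, n_boot = n_boot,
      seed = if (is.null(seed)) NULL else seed + i
    )
  })
  effects$weight <- effect_weights(effects$estimate)
  effects
}

#' Signed effect weights
#'
#' Normalises a set of effects into signed proportions of the total
#' absolute effect: `weight_j = |effect_j| / sum_k |effect_k|`, carrying
#' the sign of `effect_j`.  Used to display the relative positive/negative
#' contribution of each food group.
#'
#' @param effects Numeric vector of effects (at least one).
#' @return Signed weights summing to 1 in absolute value; all-`NA` with a
#'   warning when every effect is zero (the weights are then undefined).
#' @export
#' @examples
#' effect_weights(c(2, -1, 3)) # 1/3, -1/6, 1/2
effect_weights <- function(effects) {
  if (length(effects) == 0) abort("`effects` must contain at least one effect.")
  total <- sum(abs(effects))
  if (total == 0) {
    warn("all effects are zero; weights are undefined.")
    return(rep(NA_real_, length(effects)))
  }
  sign(effects) * abs(effects) / total
}
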