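# Supported candidate families and their stats-name stems.
DIST_FAMILIES <- c(
  normal = "norm", lognormal = "lnorm", gamma = "gamma", weibull = "weibull"
)

new_fitted_dist <- function(family, estimate, ks_statistic = NA_real_,
                            ks_p = NA_real_, method = "mle") {
  structure(
    list(family = family, estimate = estimate, ks_statistic = ks_statistic,
         ks_p = ks_p, method = method),
    class = "fitted_dist"
  )
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat("<fitted_dist>", x$family, "(", x$method, ")\n")
  print(x$estimate)
  if (is.finite(x$ks_statistic)) {
    cat("K-S statistic:", format(x$ks_statistic, digits = 4),
        " p:", format(x$ks_p, digits = 4), "\n")
  }
  invisible(x)
}

#' Select the best-fitting distribution by the Kolmogorov-Smirnov statistic
#'
#' Fits each candidate family by maximum likelihood and returns the family
#' whose fitted CDF has the smallest K-S distance from the empirical CDF.
#' Positive-support families (lognormal, gamma, Weibull) are only attempted
#' on strictly positive data.
#'
#' @param values Numeric vector, `n >= 10`, not constant.
#' @param families Candidate families, a subset of `"normal"`,
#'   `"lognormal"`, `"gamma"`, `"weibull"`.
#' @return A `fitted_dist`: `family`, MLE `estimate`, `ks_statistic`,
#'   `ks_p`.
#' @export
#' @examples
#' fit_best_distribution(rlnorm(500))$family
fit_best_distribution <- function(values,
                                  families = names(DIST_FAMILIES)) {
  families <- match.arg(families, names(DIST_FAMILIES), several.ok = TRUE)
  values <- values[!is.na(values)]
  if (length(values) < 10) abort("need at least 10 values to fit distributions.")
  if (diff(range(values)) == 0) abort("degenerate sample: all values identical.")
  if (any(values <= 0)) {
    families <- intersect(families, "normal")
    if (length(families) == 0) {
      abort("non-positive values: only the normal family is applicable.")
    }
  }
  fits <- purrr::compact(lapply(families, function(fam) {
    distr <- DIST_FAMILIES[[fam]]
    # fitdist prints optimiser failures; keep them off the console
    est <- tryCatch({
      fit <- NULL
      utils::capture.output(fit <- fitdistrplus::fitdist(values, distr),
                            file = nullfile())
      fit$estimate
    }, error = function(e) NULL)
    if (is.null(est)) {
      return(NULL)
    }
    ks <- suppressWarnings(
      do.call(ks.test, c(list(values, paste0("p", distr)), as.list(est)))
    )
    new_fitted_dist(fam, est, unname(ks$statistic), ks$p.value)
  }))
  if (length(fits) == 0) abort("all candidate fits failed.")
  fits[[which.min(vapply(fits, `[[`, 0, "ks_statistic"))]]
}

#' Fit a lognormal distribution to published quantiles
#'
#' Ordinary least squares of the log quantile values on the corresponding
#' standard-normal quantiles: the intercept estimates the log-scale mean
#' and the slope the log-scale sd.  This reconstructs a lognormal exposure
#' distribution from published summary quartiles when raw data are
#' unavailable.
#'
#' @param probs Probabilities of the quantiles (at least 2 distinct values
#'   in (0, 1)).
#' @param values The corresponding quantile values (> 0, strictly
#'   increasing with `probs`).
#' @return A `fitted_dist` with family `"lognormal"` and estimate
#'   `(meanlog, sdlog)`.
#' @export
#' @examples
#' fit_lognormal_from_quantiles(c(0.25, 0.5, 0.75), c(0.02, 0.03, 0.05))
fit_lognormal_from_quantiles <- function(probs, values) {
  if (length(probs) != length(values)) abort("`probs` and `values` must match.")
  if (length(unique(probs)) < 2) {
    abort("insufficient points: at least 2 distinct probabilities required.")
  }
  if (any(probs <= 0 | probs >= 1)) abort("`probs` must lie in (0, 1).")
  if (any(values <= 0)) abort("quantile values must be > 0.")
  o <- order(probs)
  if (any(diff(values[o]) <= 0)) abort("quantiles must be strictly increasing.")
  z <- qnorm(probs)
  fit <- lm.fit(cbind(1, z), log(values))
  est <- c(meanlog = unname(fit$coefficients[1]),
           sdlog = unname(fit$coefficients[2]))
  new_fitted_dist("lognormal", est, method = "quantile-ols")
}

#' Draw random samples from a fitted distribution
#'
#' @param fit A `fitted_dist` (from [fit_best_distribution()] or
#'   [fit_lognormal_from_quantiles()]).
#' @param n Number of draws.
#' @param seed Integer seed; `NULL` uses the current RNG.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "fitted_dist"))
  rfun <- get(paste0("r", DIST_FAMILIES[[fit$family]]), mode = "function")
  with_seed_or_current(seed, do.call(rfun, c(list(n), as.list(fit$estimate))))
}

#' Monte Carlo simulation of estimated daily intake
#'
#' Propagates variability through the reverse-dosimetry model: per
#' iteration, a creatinine-adjusted concentration (UE) is drawn from its
#' fitted distribution and an anthropometry tuple (age, sex, body weight,
#' height) from the population sampler; creatinine excretion is computed
#' deterministically from the tuple (or, alternatively, drawn from a
#' fitted CE distribution) and the intake follows as
#' `EDI = UE * CE / (F_UE * BW)`.  Non-positive body-weight draws are
#' handled by resampling (truncation at zero) and reported via a message.
#' UE is sampled independently of anthropometry, treating concentration,
#' excretion and body weight as separate variability sources.
#'
#' @param ue_fit `fitted_dist` for UE (ug/g-creatinine).
#' @param sampler Either a function `function(n)` returning a data frame
#'   with columns `age`, `sex`, `body_weight`, `height` (e.g. resampling a
#'   survey population), or such a data frame to be resampled with
#'   replacement; a single row acts as a point mass.
#' @param f_ue Urinary excretion fraction (> 0).
#' @param iterations Number of draws, at least 1000; default 10000.
#' @param seed Integer seed; `NULL` uses the current RNG.
#' @param ce_fit Optional `fitted_dist` for CE (g/day); when supplied, CE
#'   is drawn from it instead of being computed from anthropometry.
#' @return An `mc_result`: list with `draws` (tibble `ue`, `ce`,
#'   `body_weight`, `edi`), `iterations`, `f_ue`.
#' @export
monte_carlo_edi <- function(ue_fit, sampler, f_ue, iterations = 10000,
                            seed = NULL, ce_fit = NULL) {
  stopifnot(inherits(ue_fit, "fitted_dist"))
  if (iterations < 1000) abort("`iterations` must be at least 1000.")
  if (f_ue <= 0) abort("`f_ue` must be > 0.")
  draw_anth <- if (is.function(sampler)) {
    sampler
  } else {
    pool <- as_tibble(sampler)
    function(n) pool[sample.int(nrow(pool), n, replace = TRUE), ]
  }
  with_seed_or_current(seed, {
    ue <- sample_distribution(ue_fit, iterations)
    anth <- as_tibble(draw_anth(iterations))
    bad <- which(anth$body_weight <= 0)
    n_bad <- 0L
    while (length(bad) > 0) {
      n_bad <- n_bad + length(bad)
      anth[bad, ] <- draw_anth(length(bad))
      bad <- bad[anth$body_weight[bad] <= 0]
    }
    if (n_bad > 0) {
      rlang::inform(paste0("resampled ", n_bad, " non-positive body-weight draws."))
    }
    ce <- if (is.null(ce_fit)) {
      creatinine_excretion(anth$age, anth$sex, anth$body_weight, anth$height)
    } else {
      sample_distribution(ce_fit, iterations)
    }
    draws <- tibble(
      ue = ue, ce = ce, body_weight = anth$body_weight,
      edi = estimate_daily_intake(ue, ce, f_ue, anth$body_weight)
    )
    structure(
      list(draws = draws, iterations = iterations, f_ue = f_ue),
      class = "mc_result"
    )
  })
}

# Percentile grid used in probabilistic risk reporting.
RISK_PROBS <- c(p5 = 0.05, p25 = 0.25, p50 = 0.5, p75 = 0.75, p95 = 0.95)

#' Percentile summary and exceedance of probabilistic risk draws
#'
#' Converts Monte Carlo EDI draws to hazard-quotient draws against the
#' reference doses, adds the paraben hazard index per draw when all three
#' paraben analytes are present (draws paired by iteration), and reports
#' the P5/P25/P50/P75/P95 percentiles and the fraction of draws at or
#' above 1.
#'
#' @param edi_draws A data frame (or named list of equal-length vectors) of
#'   EDI draws, ug/kg-bw/day, one column per analyte.
#' @param doses Reference-dose registry, default [reference_doses()].
#' @return A tibble, one row per analyte (and one `HI_parabens` row):
#'   `quantity`, percentile columns, `exceedance`.
#' @export
probabilistic_risk_summary <- function(edi_draws, doses = reference_doses()) {
  edi_draws <- as_tibble(as.data.frame(edi_draws))
  missing_rfd <- setdiff(names(edi_draws), doses$analyte_id)
  if (length(missing_rfd) > 0) {
    abort(paste0("missing reference dose for analyte(s): ",
                 paste(missing_rfd, collapse = ", "), "."))
  }
  rfd <- setNames(doses$value, doses$analyte_id)
  hq <- purrr::imap(edi_draws, function(x, a) hazard_quotient(x, rfd[[a]]))
  if (all(PARABENS %in% names(hq))) {
    hq$HI_parabens <- hq$MP + hq$EP + hq$PP
  }
  purrr::map_dfr(hq, function(x) {
    q <- quantile(x, RISK_PROBS, names = FALSE)
    tibble(
      p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
      exceedance = mean(x >= 1)
    )
  }, .id = "quantity")
}

#' Exceedance of a reference dose from published quantiles
#'
#' Desk-scale probabilistic check: reconstructs a lognormal EDI
#' distribution from published quartiles ([fit_lognormal_from_quantiles()]),
#' draws `iterations` Monte Carlo samples, and reports the percentage of
#' draws exceeding the reference dose.
#'
#' @param probs,values Quantile pairs describing the published EDI
#'   distribution (ug/kg-bw/day).
#' @param rfd Reference dose (> 0).
#' @param rfd_units Units of `rfd`, default `"ug"` per kg-bw/day.
#' @param iterations Number of draws, default 10000.
#' @param seed Integer seed.
#' @return A list: `fit` (the lognormal `fitted_dist`), `exceedance_pct`
#'   (percentage of draws with HQ >= 1), `iterations`.
#' @export
#' @examples
#' mc_exceedance_from_quantiles(
#'   c(0.25, 0.5, 0.75), c(0.02, 0.03, 0.05),
#'   rfd = 0.2, rfd_units = "ng", seed = 1
#' )$exceedance_pct
mc_exceedance_from_quantiles <- function(probs, values, rfd,
                                         rfd_units = "ug",
                                         iterations = 10000, seed = NULL) {
  fit <- fit_lognormal_from_quantiles(probs, values)
  draws <- sample_distribution(fit, iterations, seed)
  list(
    fit = fit,
    exceedance_pct = 100 * exceedance_fraction(draws, rfd, rfd_units = rfd_units),
    iterations = iterations
  )
}
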