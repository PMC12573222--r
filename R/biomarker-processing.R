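#' Substitute values below the limit of detection
#'
#' Left-censored readings are replaced by LOD/2, the conventional
#' substitution for biomonitoring data; detected values (at or above the
#' LOD) pass through unchanged.  Vectorised; `lod` is recycled.
#'
#' @param value Raw concentration(s), ug/L; must be >= 0.
#' @param lod Limit(s) of detection, ug/L; must be > 0.
#' @return Numeric vector of the same length as `value`.
#' @export
#' @examples
#' substitute_below_lod(c(0.01, 0.05), lod = 0.03) # 0.015, 0.05
substitute_below_lod <- function(value, lod) {
  if (any(value < 0, na.rm = TRUE)) abort("`value` must be >= 0.")
  if (any(lod <= 0, na.rm = TRUE)) abort("`lod` must be > 0.")
  ifelse(value < lod, lod / 2, value)
}

#' Creatinine-adjust a urinary concentration
#'
#' Divides the concentration (ug/L) by urinary creatinine (g/L) to correct
#' for urine dilution, yielding ug/g-creatinine.
#'
#' @param concentration Concentration(s), ug/L.
#' @param creatinine Urinary creatinine, g/L; must be > 0.
#' @param subject_id Optional identifier(s) used to name offending subjects
#'   in error messages.
#' @return Adjusted concentration(s), ug/g-creatinine.
#' @export
#' @examples
#' creatinine_adjust(10, 0.5) # 20
creatinine_adjust <- function(concentration, creatinine, subject_id = NULL) {
  bad <- which(!(creatinine > 0))
  if (length(bad) > 0) {
    who <- if (is.null(subject_id)) paste("position", bad[1]) else subject_id[bad[1]]
    abort(paste0("non-positive creatinine for subject ", who, "."))
  }
  concentration / creatinine
}

#' Fraction of measurements at or above the limit of detection
#'
#' @param measurements A data frame with columns `raw_concentration` and
#'   `lod` (both ug/L), e.g. one analyte's rows from
#'   [generate_biomarkers()].
#' @return A fraction in `[0, 1]`.
#' @export
detection_rate <- function(measurements) {
  if (nrow(measurements) == 0) abort("`measurements` must be nonempty.")
  mean(measurements$raw_concentration >= measurements$lod)
}

#' Process raw biomarker measurements to analysis scale
#'
#' Applies the LOD/2 substitution on the raw ug/L scale and then
#' creatinine-adjusts, adding columns `value` (substituted, ug/L) and
#' `adjusted` (ug/g-creatinine).
#'
#' @param measurements A long biomarker table as from
#'   [generate_biomarkers()] (columns `subject_id`, `analyte_id`,
#'   `raw_concentration`, `lod`, `creatinine`).
#' @return The input with `value` and `adjusted` columns appended.
#' @export
process_biomarkers <- function(measurements) {
  measurements %>%
    mutate(
      value = substitute_below_lod(.data$raw_concentration, .data$lod),
      adjusted = creatinine_adjust(.data$value, .data$creatinine,
                                   .data$subject_id)
    )
}

#' Five-number distribution summary
#'
#' Empirical minimum, quartiles (linear interpolation between order
#' statistics) and maximum, the layout used for reporting exposure and
#' intake distributions.
#'
#' @param values Nonempty numeric vector.
#' @param units Unit label carried along in the output.
#' @return A one-row tibble: `n`, `min`, `p25`, `p50`, `p75`, `max`,
#'   `units`.
#' @export
#' @examples
#' summarize_distribution(1:5, "ug/kg-bw/day")$p50 # 3
summarize_distribution <- function(values, units = "") {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("`values` must be nonempty.")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    n = length(values), min = min(values),
    p25 = q[1], p50 = q[2], p75 = q[3],
    max = max(values), units = units
  )
}

#' Kruskal-Wallis comparison of groups
#'
#' Rank-based test (with tie correction) for a location difference between
#' two or more groups, used to compare exposure distributions across age
#' strata.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least two
#'   nonempty groups.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
compare_groups <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) abort("`compare_groups()` needs at least 2 nonempty groups.")
  kw <- kruskal.test(values, groups)
  tibble(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value
  )
}

#' Per-stratum and whole-population concentration summaries
#'
#' Summarises creatinine-adjusted concentrations per analyte within each
#' age stratum and for the total population, with a Kruskal-Wallis p-value
#' for the across-strata comparison.
#'
#' @param processed Output of [process_biomarkers()] (needs `adjusted`,
#'   `analyte_id`, `stratum`).
#' @param units Unit label, default `"ug/g-creatinine"`.
#' @return A tibble with one row per analyte x (stratum or `"total"`).
#' @export
concentration_summary <- function(processed, units = "ug/g-creatinine") {
  purrr::map_dfr(split(processed, processed$analyte_id), function(d) {
    per <- purrr::map_dfr(split(d, d$stratum), function(s) {
      summarize_distribution(s$adjusted, units)
    }, .id = "stratum")
    total <- summarize_distribution(d$adjusted, units)
    total$stratum <- "total"
    out <- bind_rows(per, total)
    out$kw_p_value <- compare_groups(d$adjusted, d$stratum)$p_value
    out
  }, .id = "analyte_id")
}
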