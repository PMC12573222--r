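#' Daily creatinine excretion (Mage equations)
#'
#' Predicts the daily urinary creatinine excretion rate (g/day) from age,
#' sex, body weight and height.  Adults (age >= 18) use the sex-specific
#' power model `CE = k * (140 - age) * BW^1.5 * ht^0.5 * 1e-6` with
#' `k = 1.93` (males) or `1.64` (females).  Minors (< 18) use height-only
#' models: males `CE = ht * (6.265 + s * (ht - 168)) * 1e-3` with slope
#' `s = 0.0564` below 168 cm and `0.2550` at or above (the two branches
#' coincide at 168 cm); females `CE = 2.045 * ht * exp(0.01552 * (ht - 90))
#' * 1e-3`.
#'
#' @param age Age in years; must satisfy `0 <= age < 140` (beyond 140 the
#'   adult model changes sign).
#' @param sex `"male"` or `"female"` (vectorised, case-insensitive).
#' @param body_weight Body weight, kg (> 0).
#' @param height Height, cm (> 0).
#' @return Creatinine excretion, g/day (strictly positive).
#' @export
#' @examples
#' creatinine_excretion(40, "male", 70, 170) # 1.4738 g/day
creatinine_excretion <- function(age, sex, body_weight, height) {
  n <- max(length(age), length(sex), length(body_weight), length(height))
  age <- rep_len(age, n)
  sex <- tolower(rep_len(as.character(sex), n))
  body_weight <- rep_len(body_weight, n)
  height <- rep_len(height, n)
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (any(age < 0 | age >= 140)) {
    abort("`age` must lie in [0, 140); the adult model is undefined beyond 140.")
  }
  if (any(body_weight <= 0) || any(height <= 0)) {
    abort("`body_weight` and `height` must be > 0.")
  }
  adult <- age >= 18
  male <- sex == "male"
  k <- ifelse(male, 1.93, 1.64)
  ce <- numeric(n)
  ce[adult] <- (k * (140 - age) * body_weight^1.5 * sqrt(height) * 1e-6)[adult]
  minor_m <- !adult & male
  slope <- ifelse(height < 168, 0.0564, 0.2550)
  ce[minor_m] <- (height * (6.265 + slope * (height - 168)) * 1e-3)[minor_m]
  minor_f <- !adult & !male
  ce[minor_f] <- (2.045 * height * exp(0.01552 * (height - 90)) * 1e-3)[minor_f]
  ce
}

#' Urinary excretion fractions
#'
#' Fraction of an ingested dose excreted in urine as the measured analyte
#' (F_UE), used to scale urinary excretion back to intake: 17.4% for MP,
#' 13.7% for EP, 8.6% for PP and 100% for BPA.
#'
#' @return A named numeric vector over the four analytes.
#' @export
excretion_fractions <- function() {
  c(MP = 0.174, EP = 0.137, PP = 0.086, BPA = 1.0)
}

#' Estimated daily intake by reverse dosimetry
#'
#' `EDI = UE * CE / (F_UE * BW)`: the creatinine-adjusted urinary
#' concentration (ug/g-creatinine) times the daily creatinine excretion
#' (g/day), divided by the urinary excretion fraction and body weight (kg),
#' giving ug/kg-bw/day.
#'
#' @param ue Creatinine-adjusted concentration, ug/g-creatinine (>= 0).
#' @param ce Daily creatinine excretion, g/day (> 0).
#' @param f_ue Urinary excretion fraction in (0, 1] (> 0).
#' @param bw Body weight, kg (> 0).
#' @return Estimated daily intake, ug/kg-bw/day.
#' @export
#' @examples
#' estimate_daily_intake(17.54, 1.4737, 0.174, 70) # ~2.12 ug/kg-bw/day
estimate_daily_intake <- function(ue, ce, f_ue, bw) {
  if (any(ue < 0)) abort("`ue` must be >= 0.")
  if (any(ce <= 0)) abort("`ce` must be > 0.")
  if (any(f_ue <= 0)) abort("`f_ue` must be > 0.")
  if (any(bw <= 0)) abort("`bw` must be > 0.")
  ue * ce / (f_ue * bw)
}

#' Subject-level estimated daily intakes
#'
#' Joins processed biomarker measurements with anthropometry, computes each
#' subject's creatinine excretion and applies the reverse-dosimetry model,
#' returning one row per subject x analyte.
#'
#' @param participants Anthropometry table (`subject_id`, `age`, `sex`,
#'   `body_weight`, `height`, and `stratum` if present).
#' @param processed Output of [process_biomarkers()] (needs `subject_id`,
#'   `analyte_id`, `adjusted`).
#' @param fractions Named F_UE vector, default [excretion_fractions()].
#' @return A tibble: `subject_id`, `stratum` (if available), `analyte_id`,
#'   `ue` (ug/g-creatinine), `ce` (g/day), `body_weight` (kg), `edi`
#'   (ug/kg-bw/day).
#' @export
edi_table <- function(participants, processed, fractions = excretion_fractions()) {
  if (nrow(processed) == 0) {
    return(tibble(
      subject_id = character(), stratum = character(),
      analyte_id = character(), ue = numeric(), ce = numeric(),
      body_weight = numeric(), edi = numeric()
    ))
  }
  missing_ids <- setdiff(processed$subject_id, participants$subject_id)
  if (length(missing_ids) > 0) {
    abort(paste0("missing anthropometry for measured subject(s): ",
                 paste(head(missing_ids, 3), collapse = ", "), "."))
  }
  unknown <- setdiff(unique(processed$analyte_id), names(fractions))
  if (length(unknown) > 0) {
    abort(paste0("no excretion fraction for analyte(s): ",
                 paste(unknown, collapse = ", "), "."))
  }
  anth <- participants %>%
    mutate(ce = creatinine_excretion(.data$age, .data$sex,
                                     .data$body_weight, .data$height))
  keep <- intersect(c("subject_id", "stratum", "ce", "body_weight"), names(anth))
  out <- processed %>%
    select(all_of(c("subject_id", "analyte_id")), ue = "adjusted") %>%
    left_join(select(anth, all_of(keep)), by = "subject_id") %>%
    mutate(edi = estimate_daily_intake(.data$ue, .data$ce,
                                       unname(fractions[.data$analyte_id]),
                                       .data$body_weight))
  cols <- intersect(c("subject_id", "stratum", "analyte_id", "ue", "ce",
                      "body_weight", "edi"), names(out))
  select(out, all_of(cols))
}

#' Per-stratum EDI distribution summaries
#'
#' Five-number summaries of estimated daily intake per analyte within each
#' age stratum and overall, with a Kruskal-Wallis p-value comparing strata.
#'
#' @param edi Output of [edi_table()] (needs `edi`, `analyte_id`,
#'   `stratum`).
#' @return A tibble, one row per analyte x (stratum or `"total"`).
#' @export
edi_summary <- function(edi) {
  purrr::map_dfr(split(edi, edi$analyte_id), function(d) {
    per <- purrr::map_dfr(split(d, d$stratum), function(s) {
      summarize_distribution(s$edi, "ug/kg-bw/day")
    }, .id = "stratum")
    total <- summarize_distribution(d$edi, "ug/kg-bw/day")
    total$stratum <- "total"
    out <- bind_rows(per, total)
    out$kw_p_value <- compare_groups(d$edi, d$stratum)$p_value
    out
  }, .id = "analyte_id")
}
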