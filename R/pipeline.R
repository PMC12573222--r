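#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it so stages
#'   are independently reproducible.
#' @param output_dir Directory for all stage outputs.
#' @param iterations Monte Carlo iterations per analyte x stratum.
#' @param n_boot Bootstrap replicates for g-computation.
#' @param alpha Significance level for the Spearman screen.
#' @param reference_doses Optional path to a YAML reference-dose registry;
#'   `NULL` uses the registry shipped with the package.
#' @param stages Stages to run, in order, a subset of `"simulate"`,
#'   `"process"`, `"dose"`, `"risk"`, `"mc"`, `"associate"`.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, output_dir = tempfile("edcrisk_"),
                            iterations = 10000, n_boot = 1000, alpha = 0.05,
                            reference_doses = NULL,
                            stages = c("simulate", "process", "dose", "risk",
                                       "mc", "associate")) {
  list(
    seed = seed, output_dir = output_dir, iterations = iterations,
    n_boot = n_boot, alpha = alpha, reference_doses = reference_doses,
    stages = match.arg(stages, several.ok = TRUE)
  )
}

# Run one stage, rethrowing any failure with the stage name attached.
run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the full biomonitoring risk pipeline
#'
#' Configuration-driven end-to-end runner: synthetic-population generation,
#' biomarker processing, reverse dosimetry, deterministic risk
#' characterisation, Monte Carlo probabilistic risk, and dietary
#' association, writing one CSV per output table plus a JSON manifest with
#' seeds, configuration hash and file checksums.  Deterministic given the
#' config (byte-identical tables across runs).
#'
#' @param config A list from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @param spec Population specification for the simulate stage, default
#'   [default_population_spec()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), spec = default_population_spec()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(pipeline_config(), config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character()
  emit <- function(tbl, name) {
    path <- file.path(config$output_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path)
    outputs[[name]] <<- path
    outputs <<- outputs
  }

  study <- NULL
  processed <- NULL
  edi <- NULL
  doses <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      study <- simulate_study(spec, seed)
      emit(study$participants, "participants")
      emit(study$intakes, "intakes")
      emit(study$biomarkers, "biomarkers")
    })
  }
  if ("process" %in% config$stages) {
    run_stage("process", {
      processed <- process_biomarkers(study$biomarkers)
      emit(concentration_summary(processed), "concentration_summary")
      rates <- purrr::map_dfr(split(study$biomarkers, study$biomarkers$analyte_id),
                              function(d) tibble(detection_rate = detection_rate(d)),
                              .id = "analyte_id")
      emit(rates, "detection_rates")
    })
  }
  if ("dose" %in% config$stages) {
    run_stage("dose", {
      edi <- edi_table(study$participants, processed)
      emit(edi, "edi")
      emit(edi_summary(edi), "edi_summary")
    })
  }
  if (any(c("risk", "mc") %in% config$stages)) {
    run_stage("risk", {
      doses <- reference_doses(config$reference_doses)
    })
  }
  if ("risk" %in% config$stages) {
    run_stage("risk", {
      emit(risk_table(edi, doses), "risk")
    })
  }
  if ("mc" %in% config$stages) {
    run_stage("mc", {
      fractions <- excretion_fractions()
      mc <- purrr::map_dfr(AGE_STRATA, function(s) {
        pool <- filter(study$participants, .data$stratum == s)
        sub <- filter(edi, .data$stratum == s)
        draws <- purrr::imap(split(sub, sub$analyte_id), function(d, a) {
          ue_fit <- fit_best_distribution(d$ue)
          mc_seed <- (derive_seed(seed, "mc") + match(s, AGE_STRATA) * 10 +
                        match(a, ANALYTES)) %% .Machine$integer.max
          res <- monte_carlo_edi(
            ue_fit, pool, fractions[[a]],
            iterations = config$iterations, seed = mc_seed
          )
          res$draws$edi
        })
        out <- probabilistic_risk_summary(draws, doses)
        out$stratum <- s
        out
      })
      emit(mc, "mc_summary")
    })
  }
  if ("associate" %in% config$stages) {
    run_stage("associate", {
      assoc_seed <- derive_seed(seed, "associate") %% (2^30)
      screens <- purrr::map_dfr(AGE_STRATA, function(s) {
        ids <- study$participants$subject_id[study$participants$stratum == s]
        sc <- spearman_matrix(
          filter(processed, .data$subject_id %in% ids),
          filter(study$intakes, .data$subject_id %in% ids)
        )
        sc$stratum <- s
        sc
      })
      emit(screens, "spearman")
      mlr <- purrr::map_dfr(AGE_STRATA, function(s) {
        ids <- study$participants$subject_id[study$participants$stratum == s]
        screen <- filter(screens, .data$stratum == s)
        sig <- significant_food_groups(screen, config$alpha)
        purrr::map_dfr(names(sig)[lengths(sig) > 0], function(a) {
          fit <- mlr_food_groups(
            filter(processed, .data$subject_id %in% ids),
            filter(study$intakes, .data$subject_id %in% ids),
            study$participants, a, sig[[a]]
          )
          fit$coefficients %>%
            mutate(analyte_id = a, stratum = s,
                   r = fit$r, r_squared = fit$r_squared)
        })
      })
      emit(mlr, "mlr")
      gcomp <- purrr::map_dfr(AGE_STRATA, function(s) {
        ids <- study$participants$subject_id[study$participants$stratum == s]
        purrr::map_dfr(ANALYTES, function(a) {
          out <- suppressWarnings(gcomputation_scan(
            filter(processed, .data$subject_id %in% ids),
            filter(study$intakes, .data$subject_id %in% ids),
            study$participants, a,
            n_boot = config$n_boot,
            seed = assoc_seed + match(s, AGE_STRATA) * 100 + match(a, ANALYTES) * 20
          ))
          out$stratum <- s
          out
        })
      })
      emit(gcomp, "gcomp")
    })
  }

  manifest <- list(
    package = "edcrisk",
    version = as.character(utils::packageVersion("edcrisk")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    stages = config$stages,
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks on the three study tables, distinguishing
#' fatal errors from warnings; returns a report rather than raising.
#'
#' @param participants,intakes,biomarkers The study tables (any may be
#'   `NULL` to skip).
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `table`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(participants = NULL, intakes = NULL,
                            biomarkers = NULL) {
  report <- list()
  note <- function(severity, table, message) {
    report[[length(report) + 1]] <<- tibble(
      severity = severity, table = table, message = message
    )
  }
  if (!is.null(participants)) {
    need <- c("subject_id", "age", "sex", "body_weight", "height")
    miss <- setdiff(need, names(participants))
    if (length(miss) > 0) {
      note("error", "participants",
           paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      if (any(participants$body_weight <= 0)) {
        note("error", "participants", "non-positive body weight.")
      }
      if (any(participants$height <= 0)) {
        note("error", "participants", "non-positive height.")
      }
      if (any(participants$age < 0 | participants$age >= 140)) {
        note("error", "participants", "age outside [0, 140).")
      }
      if (!all(tolower(participants$sex) %in% c("male", "female"))) {
        note("error", "participants", "sex must be male/female.")
      }
      if (anyDuplicated(participants$subject_id)) {
        note("warning", "participants", "duplicated subject identifiers.")
      }
    }
  }
  if (!is.null(intakes)) {
    miss <- setdiff(FOOD_GROUPS, names(intakes))
    if (length(miss) > 0) {
      note("error", "intakes",
           paste("12-group schema violated; missing:", paste(miss, collapse = ", ")))
    } else if (any(as.matrix(intakes[FOOD_GROUPS]) < 0)) {
      note("error", "intakes", "negative intake weight.")
    }
    if (!"subject_id" %in% names(intakes)) {
      note("error", "intakes", "missing column(s): subject_id")
    }
  }
  if (!is.null(biomarkers)) {
    need <- c("subject_id", "analyte_id", "raw_concentration", "lod", "creatinine")
    miss <- setdiff(need, names(biomarkers))
    if (length(miss) > 0) {
      note("error", "biomarkers",
           paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      if (any(biomarkers$raw_concentration < 0)) {
        note("error", "biomarkers", "negative raw concentration.")
      }
      if (any(biomarkers$creatinine <= 0)) {
        note("error", "biomarkers", "non-positive creatinine.")
      }
      if ("loq" %in% names(biomarkers) && any(biomarkers$lod >= biomarkers$loq)) {
        note("warning", "biomarkers", "lod not below loq.")
      }
      if ("censored" %in% names(biomarkers) &&
          !all(biomarkers$censored == (biomarkers$raw_concentration < biomarkers$lod))) {
        note("warning", "biomarkers",
             "censored flag inconsistent with raw concentration vs LOD.")
      }
    }
  }
  if (length(report) == 0) {
    tibble(severity = character(), table = character(), message = character())
  } else {
    bind_rows(report)
  }
}
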