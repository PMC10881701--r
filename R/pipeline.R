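#' Quantify every cycle of one phantom patient
#'
#' Runs the full image chain for one patient: segments each rough lesion VOI
#' at 42% of its maximum on the baseline receptor volume, then transfers all
#' VOIs onto every post-cycle emission volume through the recorded rigid
#' transform and assembles the mean- and peak-based T/N ratios.
#'
#' @param phantom A [build_phantom()] result.
#' @param threshold Segmentation threshold fraction (default 0.42).
#' @return Tibble of [quantify_patient_cycle()] rows, one pair (mean, peak)
#'   per cycle.
#' @export
quantify_phantom <- function(phantom, threshold = 0.42) {
  segmented <- lapply(phantom$rough_vois, function(rv) {
    segment_lesion_voi(phantom$baseline_volume, rv, threshold = threshold)
  })
  purrr::map_dfr(seq_along(phantom$cycle_volumes), function(cycle) {
    quantify_patient_cycle(
      cycle_volume = phantom$cycle_volumes[[cycle]],
      lesion_vois = segmented,
      lesion_lobes = phantom$lesions$lobe,
      normal_voi = phantom$normal_voi,
      ia_lobe = phantom$ia_lobe,
      transform = phantom$baseline_to_cycle_transforms[[cycle]],
      patient_id = phantom$patient_id, cycle = cycle)
  })
}

#' Run the end-to-end trial pipeline on a synthetic cohort
#'
#' Generates a cohort of phantoms (treated lobes from a permuted-block list),
#' quantifies every patient-cycle through the image chain, runs the paired,
#' ratio and mixed-model analyses on the resulting T/N table, classifies
#' per-lobe response and grades toxicity, and assembles everything into an
#' `analysis_report`. When `outdir` is given, [render_tables()] persists the
#' report tables as CSV/JSON.
#'
#' @param config A [cohort_config()].
#' @param outdir Optional output directory for rendered tables.
#' @param stages Stages to run, in order; later stages need earlier ones.
#' @return An object of class `analysis_report`.
#' @export
run_pipeline <- function(config,
                         outdir = NULL,
                         stages = c("generate", "quantify", "analyze",
                                    "report")) {
  stopifnot(inherits(config, "cohort_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  report <- structure(
    list(config = config, seed = config$seed,
         provenance = config_hash(config)),
    class = "analysis_report")

  # ---- generate ------------------------------------------------------------
  phantoms <- NULL
  if ("generate" %in% stages) {
    report$randomization <- NULL
    run_stage("generate", {
      rand <- generate_randomization(config$n_patients, seed = config$seed)
      patient_seeds <- withr::with_seed(config$seed,
                                        sample.int(2^30, config$n_patients))
      completed <- rep(config$n_cycles, config$n_patients)
      if (config$dropout && config$n_patients >= 4 && config$n_cycles >= 2) {
        early <- withr::with_seed(config$seed + 1L,
                                  sample(seq_len(config$n_patients), 3))
        completed[early] <- c(1L, 1L, 2L)
      }
      phantoms <- lapply(seq_len(config$n_patients), function(i) {
        ph <- build_phantom(config, patient_seed = patient_seeds[i],
                            ia_lobe = rand$assignments[i],
                            patient_id = sprintf("P%02d", i))
        ph$cycle_volumes <- ph$cycle_volumes[seq_len(completed[i])]
        ph$baseline_to_cycle_transforms <-
          ph$baseline_to_cycle_transforms[seq_len(completed[i])]
        ph
      })
      report$randomization <- tibble(
        patient_id = sprintf("P%02d", seq_len(config$n_patients)),
        ia_lobe = rand$assignments, completed_cycles = completed)
      report$patients <- purrr::map_dfr(phantoms, function(ph) {
        tibble(patient_id = ph$patient_id, ia_lobe = ph$ia_lobe,
               n_lesions = nrow(ph$lesions),
               tumour_burden_ml = sum(vapply(ph$lesion_vois, voi_volume_ml,
                                             numeric(1))),
               hypervascular = ph$hypervascular)
      })
      report$diameters <- purrr::map_dfr(seq_along(phantoms), function(i) {
        withr::with_seed(patient_seeds[i] + 1L,
                         simulate_followup(phantoms[[i]], config))
      })
      report$labs <- purrr::map_dfr(seq_along(phantoms), function(i) {
        withr::with_seed(patient_seeds[i] + 2L,
                         simulate_labs(phantoms[[i]], config))
      })
    })
  }

  # ---- quantify ------------------------------------------------------------
  if ("quantify" %in% stages) {
    if (is.null(phantoms)) {
      abort("Pipeline stage 'quantify' needs the 'generate' stage.")
    }
    run_stage("quantify", {
      report$tn <- purrr::map_dfr(phantoms, quantify_phantom)
    })
  }

  # ---- analyze ------------------------------------------------------------
  if ("analyze" %in% stages) {
    if (is.null(report$tn)) {
      abort("Pipeline stage 'analyze' needs the 'quantify' stage.")
    }
    run_stage("analyze", {
      tn <- report$tn
      report$primary <- paired_t_test(tn, cycle = 1L, basis = "mean")
      report$ratio <- log_ratio_test(tn, cycle = 1L, basis = "mean")
      report$proportion_increased <- proportion_increased(tn, cycle = 1L,
                                                          basis = "mean")
      report$lmm_all_cycles <- fit_two_level_lmm(tn, basis = "mean")
      report$primary_peak <- paired_t_test(tn, cycle = 1L, basis = "peak")
      report$ratio_peak <- log_ratio_test(tn, cycle = 1L, basis = "peak")
      covars <- dplyr::left_join(tn, report$patients, by = "patient_id")
      report$covariates <- purrr::map_dfr(
        c("hypervascular", "ia_lobe", "tumour_burden_ml"),
        function(cv) {
          tryCatch(covariate_test(covars, cv), error = function(e) {
            inform(sprintf("Covariate '%s' not testable: %s", cv,
                           conditionMessage(e)))
            tibble(covariate = cv, statistic = NA_real_, p_value = NA_real_)
          })
        })
      resp <- assess_response(report$diameters)
      report$response_table <- classify_cohort_response(resp,
                                                        report$randomization)
      report$response_p <- response_table_pvalues(report$response_table)
      report$toxicity_events <- attribute_toxicity(report$labs)
      report$toxicity_table <- toxicity_table(report$toxicity_events)
    })
  }

  # ---- report --------------------------------------------------------------
  if ("report" %in% stages && !is.null(outdir)) {
    run_stage("report", render_tables(report, outdir))
  }
  report
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$response_profile <- as.data.frame(cfg$response_profile)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  writeLines(json, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d patients, seed %d, config %s\n",
              x$config$n_patients, x$seed, substr(x$provenance, 1, 8)))
  if (!is.null(x$primary)) {
    cat("\nPrimary endpoint (cycle 1, mean basis):\n  ")
    print(x$primary)
    cat("Relative difference:\n  ")
    print(x$ratio)
    cat(sprintf("Any T/N increase: %d/%d (%.0f%%)\n",
                x$proportion_increased$n_increased,
                x$proportion_increased$n,
                100 * x$proportion_increased$proportion))
    cat("All cycles:\n  ")
    print(x$lmm_all_cycles)
  }
  invisible(x)
}

#' Persist report tables
#'
#' Writes the per-cycle T/N table, baseline characteristics, the per-timepoint
#' response table with its Fisher p-values, the toxicity table and a JSON
#' block of all estimates into `dir`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble of the files written.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(report$tn)) put(report$tn, "tn_per_cycle.csv")
  if (!is.null(report$patients)) {
    put(dplyr::left_join(report$patients,
                         report$randomization[, c("patient_id",
                                                  "completed_cycles")],
                         by = "patient_id"),
        "baseline_characteristics.csv")
  }
  if (!is.null(report$response_table)) {
    put(dplyr::left_join(report$response_table, report$response_p,
                         by = "timepoint"),
        "response_table.csv")
  }
  if (!is.null(report$toxicity_table)) {
    put(report$toxicity_table, "toxicity_table.csv")
  }
  if (!is.null(report$primary)) {
    blocks <- list(
      seed = report$seed, config_hash = report$provenance,
      primary_paired_t = as.list(tidy(report$primary)),
      ratio_test = as.list(tidy(report$ratio)),
      proportion_increased = as.list(report$proportion_increased),
      lmm_all_cycles = as.list(tidy(report$lmm_all_cycles)),
      primary_peak = as.list(tidy(report$primary_peak)),
      ratio_peak = as.list(tidy(report$ratio_peak)),
      covariates = report$covariates,
      response_p = report$response_p
    )
    p <- file.path(dir, "report.json")
    jsonlite::write_json(blocks, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths[["report.json"]] <- p
  }
  invisible(tibble(file = names(paths), path = unname(paths)))
}
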