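#' Configuration of a synthetic within-patient uptake cohort
#'
#' Bundles every parameter of the phantom and cohort generator. Defaults are
#' calibrated so that the simulated cohort has the statistical structure of a
#' 27-patient within-patient lobe-randomized uptake trial: a control-lobe
#' tumour-to-non-tumour (T/N) ratio with geometric mean 16.2, a multiplicative
#' intra-arterial enhancement with geometric mean 1.17, and a within-pair
#' log-ratio standard deviation of 0.39 (see the methods vignette for the
#' derivations).
#'
#' @param n_patients Number of patients.
#' @param n_cycles Treatment cycles per patient (each yields one post-cycle
#'   emission volume).
#' @param grid_shape Integer triple: voxels per axis.
#' @param voxel_spacing mm triple.
#' @param background_counts Expected counts/voxel in healthy liver; `> 0`.
#' @param tn_true_log_mean Log of the geometric-mean control-lobe T/N.
#' @param tn_true_log_sd Between-patient SD of log T/N.
#' @param tn_cycle_log_sd Within-patient, between-cycle SD of log T/N (a
#'   common drift applied to both lobes, so the within-patient ratio is
#'   unaffected).
#' @param enhancement_log_mean Log of the geometric-mean multiplicative
#'   intra-arterial enhancement rho.
#' @param enhancement_log_sd SD of log rho across patient-cycles; this is the
#'   within-pair SD of the log T/N ratio seen by the paired analyses.
#' @param lesions_per_lobe_range Integer pair within `[1, 3]`.
#' @param lesion_diameter_range mm pair; lower bound at least 30 (eligibility
#'   requires one metastasis of at least 3 cm per lobe).
#' @param lesion_multiplier_sd Per-lesion log-scale jitter around the
#'   patient-level uptake multiplier. The default 0 makes all lesions of a
#'   patient share one multiplier, so the noise-free T/N ratio between lobes
#'   equals rho exactly.
#' @param misalignment_max_translation mm; 0 (default) keeps all post-cycle
#'   grids aligned with baseline.
#' @param misalignment_max_rotation_deg Degrees; 0 by default.
#' @param noise Poisson count noise on all volumes; `FALSE` gives the
#'   noise-free expectation volumes.
#' @param response_profile Tibble describing per-lobe diameter-response types;
#'   see [default_response_profile()].
#' @param dropout Simulate early discontinuation (two patients after cycle 1,
#'   one after cycle 2) when `TRUE`; off by default.
#' @param lab_abnormal_prob Probability that a patient's baseline value of an
#'   analyte is outside its normal range.
#' @param lab_emergent_prob Probability of a treatment-emergent excursion per
#'   patient-analyte.
#' @param lab_drift_sd Log-scale SD of visit-to-visit laboratory drift.
#' @param seed Integer seed recorded in every output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 27,
                          n_cycles = 4,
                          grid_shape = c(64, 64, 64),
                          voxel_spacing = c(4, 4, 4),
                          background_counts = 30,
                          tn_true_log_mean = log(16.2),
                          tn_true_log_sd = 0.90,
                          tn_cycle_log_sd = 0.35,
                          enhancement_log_mean = log(1.17),
                          enhancement_log_sd = 0.39,
                          lesions_per_lobe_range = c(1, 3),
                          lesion_diameter_range = c(30, 50),
                          lesion_multiplier_sd = 0,
                          misalignment_max_translation = 0,
                          misalignment_max_rotation_deg = 0,
                          noise = TRUE,
                          response_profile = default_response_profile(),
                          dropout = FALSE,
                          lab_abnormal_prob = 0.15,
                          lab_emergent_prob = 0.05,
                          lab_drift_sd = 0.08,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_cycles = as.integer(n_cycles),
    grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    background_counts = background_counts,
    tn_true_log_mean = tn_true_log_mean, tn_true_log_sd = tn_true_log_sd,
    tn_cycle_log_sd = tn_cycle_log_sd,
    enhancement_log_mean = enhancement_log_mean,
    enhancement_log_sd = enhancement_log_sd,
    lesions_per_lobe_range = as.integer(lesions_per_lobe_range),
    lesion_diameter_range = as.numeric(lesion_diameter_range),
    lesion_multiplier_sd = lesion_multiplier_sd,
    misalignment_max_translation = misalignment_max_translation,
    misalignment_max_rotation_deg = misalignment_max_rotation_deg,
    noise = isTRUE(noise), response_profile = response_profile,
    dropout = isTRUE(dropout),
    lab_abnormal_prob = lab_abnormal_prob,
    lab_emergent_prob = lab_emergent_prob, lab_drift_sd = lab_drift_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_patients < 1) abort("`n_patients` must be at least 1.")
  if (cfg$n_patients < 2) {
    warn("A single-patient cohort is valid for generation, but paired analyses require n >= 2.")
  }
  if (cfg$n_cycles < 1) abort("`n_cycles` must be at least 1.")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 16)) {
    abort("`grid_shape` must be three integers >= 16.")
  }
  if (any(cfg$voxel_spacing <= 0)) abort("`voxel_spacing` must be positive.")
  if (cfg$background_counts <= 0) {
    abort("`background_counts` must be strictly positive.")
  }
  if (any(cfg$lesions_per_lobe_range < 1) || any(cfg$lesions_per_lobe_range > 3) ||
        cfg$lesions_per_lobe_range[1] > cfg$lesions_per_lobe_range[2]) {
    abort("`lesions_per_lobe_range` must be an ordered pair within [1, 3].")
  }
  if (cfg$lesion_diameter_range[1] < 30) {
    abort("Lesion diameters must be at least 30 mm (eligibility: >= 3 cm per lobe).")
  }
  if (cfg$lesion_diameter_range[1] > cfg$lesion_diameter_range[2]) {
    abort("`lesion_diameter_range` must be ordered.")
  }
  if (cfg$tn_true_log_sd < 0 || cfg$enhancement_log_sd < 0 ||
        cfg$tn_cycle_log_sd < 0 || cfg$lesion_multiplier_sd < 0) {
    abort("Log-scale standard deviations must be non-negative.")
  }
  # the liver ellipsoid plus the largest lesion must fit inside the grid
  extent <- (cfg$grid_shape - 1) * cfg$voxel_spacing
  axes <- liver_semi_axes(extent)
  if (any(2 * axes > extent)) {
    abort("Grid too small to contain the liver ellipsoid with a margin.")
  }
  if (cfg$lesion_diameter_range[2] > 2 * min(axes) * 0.9) {
    abort("Largest lesion diameter does not fit inside the liver ellipsoid.")
  }
  structure(cfg, class = "cohort_config")
}

# liver ellipsoid semi-axes (mm), scaled to the grid extent with margin
liver_semi_axes <- function(extent_mm) {
  pmin(c(110, 75, 60), extent_mm * 0.44)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_config> %d patients x %d cycles, grid %s @ %s mm\n",
           "  control T/N ~ logN(%.3f, %.2f), enhancement ~ logN(%.3f, %.2f), ",
           "noise %s, seed %d\n"),
    x$n_patients, x$n_cycles, paste(x$grid_shape, collapse = "x"),
    paste(x$voxel_spacing, collapse = "x"),
    x$tn_true_log_mean, x$tn_true_log_sd,
    x$enhancement_log_mean, x$enhancement_log_sd,
    if (x$noise) "on" else "off", x$seed))
  invisible(x)
}

# membership helpers over world-coordinate points (n x 3 matrices)
in_ellipsoid <- function(points, centre, axes) {
  rowSums(sweep(sweep(points, 2, centre, `-`), 2, axes, `/`)^2) <= 1
}

grid_world <- function(grid_shape, spacing, origin = c(0, 0, 0)) {
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  index_to_world(idx, origin, spacing)
}

#' Build one patient phantom
#'
#' Constructs a bilobar liver (an ellipsoid split by a sagittal plane into a
#' left lobe of about one third and a right lobe of about two thirds of the
#' volume), places 1-3 spherical lesions of at least 3 cm per lobe, draws a
#' lesion-free normal-tissue region of at least 15 mL in the control lobe, and
#' renders the baseline receptor volume plus one emission volume per treatment
#' cycle. In lesion voxels the expected value is
#' `background_counts * uptake_multiplier` (control lobe) times the
#' patient-cycle enhancement `rho` in the intra-arterially treated lobe;
#' elsewhere in the liver it is `background_counts`. With `noise = TRUE` the
#' observed voxels are independent Poisson draws of those expectations.
#'
#' @param config A [cohort_config()].
#' @param patient_seed Integer seed making this patient reproducible.
#' @param ia_lobe Treated lobe; drawn by a fair coin when `NULL`.
#' @param patient_id Identifier copied into outputs.
#' @param max_attempts Placement attempts per lesion before a placement
#'   failure is raised.
#' @return An object of class `patient_phantom`: liver/lobe geometry, lesion
#'   table and VOIs (true and rough), normal-tissue VOI, per-cycle true
#'   enhancements, baseline and cycle volumes, and the baseline-to-cycle rigid
#'   transforms.
#' @export
build_phantom <- function(config, patient_seed, ia_lobe = NULL,
                          patient_id = "P01", max_attempts = 200) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(as.integer(patient_seed), {
    sp <- config$voxel_spacing
    d <- config$grid_shape
    extent <- (d - 1) * sp
    centre <- extent / 2
    axes <- liver_semi_axes(extent)
    w <- grid_world(d, sp)
    liver <- in_ellipsoid(w, centre, axes)
    # sagittal split: the upper-x third of the liver volume is the left lobe
    plane_x <- unname(quantile(w[liver, 1], 2 / 3))
    lobe_of <- function(points) {
      ifelse(points[, 1] > plane_x, "left", "right")
    }
    if (is.null(ia_lobe)) {
      ia_lobe <- sample(c("left", "right"), 1)
    }
    ia_lobe <- match.arg(ia_lobe, c("left", "right"))
    control_lobe <- setdiff(c("left", "right"), ia_lobe)

    hypervascular <- runif(1) < 0.5
    mult_patient <- exp(rnorm(1, config$tn_true_log_mean, config$tn_true_log_sd))
    rho <- exp(rnorm(config$n_cycles, config$enhancement_log_mean,
                     config$enhancement_log_sd))
    drift <- exp(rnorm(config$n_cycles, 0, config$tn_cycle_log_sd))

    # ---- lesion placement -------------------------------------------------
    n_per_lobe <- sample(seq(config$lesions_per_lobe_range[1],
                             config$lesions_per_lobe_range[2]), 2,
                         replace = TRUE)
    lesions <- list()
    for (lobe in c("left", "right")) {
      n_lobe <- n_per_lobe[[match(lobe, c("left", "right"))]]
      for (l in seq_len(n_lobe)) {
        c_try <- NULL
        for (a in seq_len(max_attempts)) {
          diameter <- runif(1, config$lesion_diameter_range[1],
                            config$lesion_diameter_range[2])
          r <- diameter / 2
          shrunk <- axes - r
          if (any(shrunk <= 0)) next
          # feasible centres: sphere inside the (conservatively eroded)
          # ellipsoid and fully on the lobe's side of the split plane, with a
          # one-voxel buffer so lesions of opposite lobes can never become
          # 26-adjacent (threshold segmentation must not merge them)
          buffer <- r + max(sp)
          on_side <- if (lobe == "left") w[, 1] - plane_x >= buffer else
            plane_x - w[, 1] >= buffer
          feasible <- which(on_side & in_ellipsoid(w, centre, shrunk))
          if (length(feasible) > 0) {
            c_try <- w[feasible[sample.int(length(feasible), 1)], ]
            break
          }
        }
        if (is.null(c_try)) {
          abort(sprintf(
            "Could not place a %d-%d mm lesion in the %s lobe after %d attempts.",
            round(config$lesion_diameter_range[1]),
            round(config$lesion_diameter_range[2]), lobe, max_attempts))
        }
        lesions[[length(lesions) + 1]] <- tibble(
          lesion_id = sprintf("%s_%d", lobe, l), lobe = lobe,
          cx = c_try[1], cy = c_try[2], cz = c_try[3], diameter = diameter,
          uptake_multiplier = mult_patient *
            exp(rnorm(1, 0, config$lesion_multiplier_sd))
        )
      }
    }
    lesions <- dplyr::bind_rows(lesions)

    # ---- expectation field (baseline world frame) -------------------------
    lesion_centres <- as.matrix(lesions[, c("cx", "cy", "cz")])
    lesion_radii <- lesions$diameter / 2
    expectation_at <- function(points, cycle = NULL) {
      ex <- ifelse(in_ellipsoid(points, centre, axes),
                   config$background_counts, 0)
      lob <- lobe_of(points)
      for (j in seq_len(nrow(lesions))) {
        inside <- rowSums(sweep(points, 2, lesion_centres[j, ], `-`)^2) <=
          lesion_radii[j]^2
        if (!any(inside)) next
        m <- lesions$uptake_multiplier[j]
        if (!is.null(cycle)) {
          m <- m * drift[cycle] *
            ifelse(lob[inside] == ia_lobe, rho[cycle], 1)
        }
        ex[inside] <- pmax(ex[inside], config$background_counts * m)
      }
      ex
    }
    render <- function(ex, grid_id) {
      vals <- if (config$noise) rpois(length(ex), ex) else ex
      spect_volume(array(vals, d), spacing = sp, grid_id = grid_id)
    }
    baseline_volume <- render(expectation_at(w), "baseline")

    transforms <- lapply(seq_len(config$n_cycles), function(cycle) {
      if (config$misalignment_max_translation > 0 ||
            config$misalignment_max_rotation_deg > 0) {
        random_rigid_transform(config$misalignment_max_translation,
                               config$misalignment_max_rotation_deg)
      } else {
        rigid_transform()
      }
    })
    cycle_volumes <- lapply(seq_len(config$n_cycles), function(cycle) {
      # cycle grids share voxel geometry; patient pose differs by transforms[[cycle]]
      back <- apply_transform(invert_transform(transforms[[cycle]]), w)
      render(expectation_at(back, cycle = cycle), paste0("cycle_", cycle))
    })

    # ---- VOIs --------------------------------------------------------------
    idx_all <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                     k = seq_len(d[3])))
    lesion_vois <- lapply(seq_len(nrow(lesions)), function(j) {
      inside <- rowSums(sweep(w, 2, lesion_centres[j, ], `-`)^2) <=
        lesion_radii[j]^2
      voi(idx_all[inside, , drop = FALSE], grid_id = "baseline",
          label = lesions$lesion_id[j], spacing = sp)
    })
    rough_vois <- lapply(seq_len(nrow(lesions)), function(j) {
      inside <- rowSums(sweep(w, 2, lesion_centres[j, ], `-`)^2) <=
        (lesion_radii[j] + 8)^2
      voi(idx_all[inside, , drop = FALSE], grid_id = "baseline",
          label = lesions$lesion_id[j], spacing = sp)
    })
    names(lesion_vois) <- names(rough_vois) <- lesions$lesion_id

    # normal tissue: control lobe, >= 8 mm clear of every lesion surface
    margin <- 8
    clear <- rep(TRUE, nrow(w))
    for (j in seq_len(nrow(lesions))) {
      clear <- clear & rowSums(sweep(w, 2, lesion_centres[j, ], `-`)^2) >
        (lesion_radii[j] + margin)^2
    }
    eligible <- liver & clear & (lobe_of(w) == control_lobe)
    n_needed <- ceiling(15000 / prod(sp))
    if (sum(eligible) < n_needed) {
      abort("Not enough lesion-free control-lobe tissue for a 15 mL normal VOI.")
    }
    elig_w <- w[eligible, , drop = FALSE]
    # grow a compact blob around the eligible voxel deepest inside the region
    if (nrow(lesions) > 0) {
      dmin <- do.call(pmin, lapply(seq_len(nrow(lesions)), function(j) {
        sqrt(rowSums(sweep(elig_w, 2, lesion_centres[j, ], `-`)^2)) -
          lesion_radii[j]
      }))
    } else {
      dmin <- rep(Inf, nrow(elig_w))
    }
    seed_pt <- elig_w[which.max(dmin), ]
    ord <- order(rowSums(sweep(elig_w, 2, seed_pt, `-`)^2))
    normal_voi <- voi(idx_all[eligible, , drop = FALSE][ord[seq_len(n_needed)], ,
                                                        drop = FALSE],
                      grid_id = "baseline", label = "normal", spacing = sp)

    liver_voi <- voi(idx_all[liver, , drop = FALSE], grid_id = "baseline",
                     label = "liver", spacing = sp)
    lobe_labels <- array(0L, d)
    lobe_labels[liver] <- ifelse(w[liver, 1] > plane_x, 1L, 2L)

    structure(
      list(patient_id = patient_id, grid_shape = d, voxel_spacing = sp,
           liver_mask = liver_voi,
           lobe_labels = spect_volume(lobe_labels, spacing = sp,
                                      grid_id = "baseline"),
           plane_x = plane_x, lesions = lesions, lesion_vois = lesion_vois,
           rough_vois = rough_vois, normal_voi = normal_voi,
           ia_lobe = ia_lobe, control_lobe = control_lobe,
           hypervascular = hypervascular,
           true_tn = lesions$uptake_multiplier, true_enhancement = rho,
           cycle_drift = drift, baseline_volume = baseline_volume,
           cycle_volumes = cycle_volumes,
           baseline_to_cycle_transforms = transforms,
           patient_seed = as.integer(patient_seed)),
      class = "patient_phantom"
    )
  })
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat(sprintf(
    "<patient_phantom '%s'> IA lobe: %s; %d lesions; %d cycle volumes; grid %s\n",
    x$patient_id, x$ia_lobe, nrow(x$lesions), length(x$cycle_volumes),
    paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Default per-lobe diameter response profile
#'
#' A mixture of response trajectories applied independently to each lobe (the
#' same profile in both lobes: the generator's null of no differential
#' response). Fractional diameter changes at 3 and 6 months are drawn from a
#' normal around the type's means. The default mixture yields, in expectation,
#' 25% partial responses at 3 months and 35% partial responses, 61% stable
#' disease and 4% progression at 6 months.
#'
#' @return A tibble with columns `type`, `prob`, `change_3mo`, `change_6mo`,
#'   `sd`.
#' @export
default_response_profile <- function() {
  tibble(
    type = c("pr", "late_pr", "sd", "pd"),
    prob = c(0.25, 0.10, 0.61, 0.04),
    change_3mo = c(-0.35, -0.20, -0.05, 0.05),
    change_6mo = c(-0.42, -0.35, -0.08, 0.30),
    sd = c(0.02, 0.03, 0.05, 0.04)
  )
}

#' Simulate follow-up lesion diameters
#'
#' Draws one response type per lobe from the configured profile and applies
#' its fractional diameter change (plus noise) to every target lesion of that
#' lobe at 3 and 6 months.
#'
#' @param phantom A [build_phantom()] result.
#' @param config The [cohort_config()] used to build it.
#' @return Tibble: `patient_id`, `lobe`, `lesion_id`, `diameter_baseline`,
#'   `diameter_3mo`, `diameter_6mo` (mm).
#' @export
simulate_followup <- function(phantom, config) {
  profile <- config$response_profile
  if (abs(sum(profile$prob) - 1) > 1e-8) {
    abort("Response profile probabilities must sum to 1.")
  }
  purrr::map_dfr(c("left", "right"), function(lobe) {
    les <- dplyr::filter(phantom$lesions, .data$lobe == !!lobe)
    type <- sample(profile$type, 1, prob = profile$prob)
    row <- profile[profile$type == type, ]
    ch3 <- rnorm(1, row$change_3mo, row$sd)
    ch6 <- rnorm(1, row$change_6mo, row$sd)
    tibble(
      patient_id = phantom$patient_id, lobe = lobe,
      lesion_id = les$lesion_id,
      diameter_baseline = les$diameter,
      diameter_3mo = pmax(1, les$diameter * (1 + ch3)),
      diameter_6mo = pmax(1, les$diameter * (1 + ch6))
    )
  })
}

#' Simulate a laboratory panel time series
#'
#' Generates per-visit values for every analyte of the grading table: a
#' baseline value (possibly abnormal), one value per treatment cycle and two
#' follow-up visits, following a multiplicative random walk with optional
#' treatment-emergent excursions.
#'
#' @param phantom A [build_phantom()] result (only identifiers are used).
#' @param config A [cohort_config()].
#' @param rules Grading rule table; see [default_grading_rules()].
#' @return Tibble: `patient_id`, `visit`, `analyte`, `value`.
#' @export
simulate_labs <- function(phantom, config, rules = default_grading_rules()) {
  visits <- c("baseline", paste0("cycle_", seq_len(config$n_cycles)),
              "fu_3mo", "fu_6mo")
  purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    mid <- (r$lln + r$uln) / 2
    base <- if (runif(1) < config$lab_abnormal_prob) {
      if (r$direction == "high") r$uln * exp(runif(1, 0.1, 1.2))
      else r$lln * exp(-runif(1, 0.1, 0.8))
    } else {
      runif(1, r$lln + 0.05 * (r$uln - r$lln), r$uln - 0.05 * (r$uln - r$lln))
    }
    drift <- exp(cumsum(c(0, rnorm(length(visits) - 1, 0, config$lab_drift_sd))))
    vals <- base * drift
    if (runif(1) < config$lab_emergent_prob) {
      hit <- sample(seq(2, length(visits)), 1)
      bump <- exp(runif(1, 0.5, 1.2))
      vals[hit] <- if (r$direction == "high") vals[hit] * bump else
        vals[hit] / bump
    }
    tibble(patient_id = phantom$patient_id, visit = visits,
           analyte = r$analyte, value = pmax(vals, mid * 0.01))
  })
}

#' Simulate the tabular T/N layer of a cohort
#'
#' Draws per patient-cycle T/N pairs directly from the generator's
#' distributional model, bypassing image rendering: the log control-lobe T/N
#' is `tn_log_mean` plus a patient-level and a cycle-level normal deviate, and
#' the log treated-lobe T/N adds `enhancement_log_mean` plus a pair-level
#' deviate with SD `enhancement_log_sd`. This is the layer on which replicated
#' operating-characteristic studies (type-I error, parameter recovery) run;
#' its structure is identical by construction to what the image chain
#' measures.
#'
#' @param n_patients,n_cycles Cohort dimensions.
#' @param tn_log_mean,tn_between_sd,tn_cycle_sd Control-lobe log T/N model.
#' @param enhancement_log_mean,enhancement_log_sd Log-enhancement model; the
#'   within-pair log-ratio SD equals `enhancement_log_sd`.
#' @param dropout When `TRUE` and `n_patients >= 4`, two random patients stop
#'   after cycle 1 and one after cycle 2.
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `cycle`, `basis`, `tn_control`, `tn_ia`.
#' @export
simulate_tn_cohort <- function(n_patients = 27, n_cycles = 4,
                               tn_log_mean = log(16.2),
                               tn_between_sd = 0.90, tn_cycle_sd = 0.35,
                               enhancement_log_mean = log(1.17),
                               enhancement_log_sd = 0.39,
                               dropout = FALSE, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    a_p <- rnorm(n_patients, 0, tn_between_sd)
    out <- tidyr::expand_grid(patient = seq_len(n_patients),
                              cycle = seq_len(n_cycles))
    log_control <- tn_log_mean + a_p[out$patient] +
      rnorm(nrow(out), 0, tn_cycle_sd)
    log_ratio <- rnorm(nrow(out), enhancement_log_mean, enhancement_log_sd)
    res <- tibble(
      patient_id = sprintf("P%02d", out$patient),
      cycle = as.integer(out$cycle), basis = "mean",
      tn_control = exp(log_control),
      tn_ia = exp(log_control + log_ratio)
    )
    if (dropout && n_patients >= 4) {
      early <- sample(seq_len(n_patients), 3)
      keep_until <- rep(n_cycles, n_patients)
      keep_until[early] <- c(1L, 1L, 2L)
      res <- dplyr::filter(res, .data$cycle <=
                             keep_until[match(.data$patient_id,
                                              sprintf("P%02d", seq_len(n_patients)))])
    }
    res
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Builds one phantom per patient (treated lobe from a permuted-block
#' randomization list), writes NIfTI volumes and VOI label maps, and CSV
#' manifests for randomization, lesions, follow-up diameters and laboratory
#' values, plus a JSON echo of the configuration. Identical `(config, seed)`
#' produce byte-identical CSV manifests.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of tibbles: `randomization`, `lesions`,
#'   `diameters`, `labs`, `files` (paths of all volumes written).
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rand <- generate_randomization(config$n_patients, seed = config$seed)
  patient_seeds <- withr::with_seed(config$seed,
                                    sample.int(2^30, config$n_patients))
  completed <- rep(config$n_cycles, config$n_patients)
  if (config$dropout && config$n_patients >= 4 && config$n_cycles >= 2) {
    early <- withr::with_seed(config$seed + 1L,
                              sample(seq_len(config$n_patients), 3))
    completed[early] <- c(1L, 1L, 2L)
  }
  lesions <- list(); diameters <- list(); labs <- list(); files <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    ph <- build_phantom(config, patient_seed = patient_seeds[i],
                        ia_lobe = rand$assignments[i], patient_id = pid)
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    paths <- c(baseline = file.path(pdir, "baseline.nii.gz"))
    write_volume(ph$baseline_volume, paths[["baseline"]])
    for (cycle in seq_len(completed[i])) {
      p <- file.path(pdir, sprintf("cycle_%d.nii.gz", cycle))
      write_volume(ph$cycle_volumes[[cycle]], p)
      paths[[sprintf("cycle_%d", cycle)]] <- p
    }
    labmap <- vois_to_labelmap(c(ph$lesion_vois, list(normal = ph$normal_voi)),
                               ph$baseline_volume)
    paths[["labels"]] <- file.path(pdir, "voi_labels.nii.gz")
    write_volume(labmap, paths[["labels"]])
    lesions[[i]] <- dplyr::mutate(ph$lesions, patient_id = pid,
                                  .before = 1)
    fu_seed <- patient_seeds[i] + 1L
    diameters[[i]] <- withr::with_seed(fu_seed, simulate_followup(ph, config))
    labs[[i]] <- withr::with_seed(fu_seed + 1L, simulate_labs(ph, config))
    files[[i]] <- tibble(patient_id = pid, item = names(paths),
                         path = unname(paths))
  }
  out <- list(
    randomization = dplyr::mutate(
      tibble(patient_id = sprintf("P%02d", seq_len(config$n_patients)),
             ia_lobe = rand$assignments,
             completed_cycles = completed),
      seed = config$seed),
    lesions = dplyr::bind_rows(lesions),
    diameters = dplyr::bind_rows(diameters),
    labs = dplyr::bind_rows(labs),
    files = dplyr::bind_rows(files)
  )
  write.csv(out$randomization, file.path(dir, "randomization.csv"),
            row.names = FALSE)
  write.csv(out$lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  write.csv(out$diameters, file.path(dir, "diameters.csv"), row.names = FALSE)
  write.csv(out$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  cfg <- unclass(config)
  cfg$response_profile <- as.data.frame(cfg$response_profile)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}
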