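#' Adaptive threshold segmentation of a lesion VOI
#'
#' Shrinks a rough VOI drawn around a lesion on the baseline receptor image to
#' the voxels whose value is at least `threshold` times the maximum voxel value
#' inside the rough VOI, restricted to the 26-connected component that contains
#' the maximum voxel. The maximum voxel is always part of the result. Where
#' several voxels tie for the maximum, the one with the lowest lexicographic
#' (z, y, x) index seeds the component.
#'
#' @param baseline_volume The baseline receptor image ([spect_volume()]) on
#'   which the threshold is computed.
#' @param rough_voi A non-empty [voi()] drawn loosely around the lesion, on the
#'   baseline grid.
#' @param threshold Fraction of the maximum voxel value; default 0.42.
#' @return A [voi()] on the baseline grid, a subset of `rough_voi`.
#' @export
segment_lesion_voi <- function(baseline_volume, rough_voi, threshold = 0.42) {
  vals <- voi_values(baseline_volume, rough_voi)
  mx <- max(vals)
  if (mx <= 0) {
    abort(sprintf("Rough VOI '%s' has no signal (maximum voxel value is %g).",
                  rough_voi$label, mx))
  }
  keep <- vals >= threshold * mx
  cand <- rough_voi$indices[keep, , drop = FALSE]
  seed <- lex_first(rough_voi$indices[vals == mx, , drop = FALSE])
  comp <- connected_component_26(cand, seed)
  voi(comp, grid_id = rough_voi$grid_id, label = rough_voi$label,
      spacing = rough_voi$spacing, origin = rough_voi$origin)
}

# lowest lexicographic (z, y, x) row of an index matrix
lex_first <- function(indices) {
  o <- order(indices[, 3], indices[, 2], indices[, 1])
  indices[o[1], ]
}

# 26-connected component of `seed` within the voxel set `indices` (n x 3)
connected_component_26 <- function(indices, seed) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pool <- setNames(rep(FALSE, nrow(indices)), key(indices))
  frontier <- matrix(seed, ncol = 3)
  pool[key(frontier)] <- TRUE
  out <- frontier
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                   drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
    nb <- unique(nb)
    hit <- match(key(nb), names(pool))
    present <- !is.na(hit)
    hit <- hit[present]
    nb <- nb[present, , drop = FALSE]
    fresh <- !pool[hit]
    pool[hit[fresh]] <- TRUE
    frontier <- nb[fresh, , drop = FALSE]
    out <- rbind(out, frontier)
  }
  storage.mode(out) <- "integer"
  out
}

#' Transfer a VOI onto another grid through a rigid transform
#'
#' Each source voxel centre is mapped through `transform` (source world to
#' target world) and assigned to the nearest voxel of the target grid.
#' Duplicate target voxels are collapsed; points falling outside the target
#' grid are dropped (their count is reported via a message).
#'
#' @param x A [voi()] with source-grid geometry.
#' @param transform A [rigid_transform()] mapping source world coordinates to
#'   target world coordinates.
#' @param target_volume A [spect_volume()] defining the target grid.
#' @return A [voi()] on the target grid.
#' @export
transfer_voi <- function(x, transform, target_volume) {
  stopifnot(inherits(x, "voi"), inherits(transform, "rigid_transform"),
            inherits(target_volume, "spect_volume"))
  w <- index_to_world(x$indices, x$origin, x$spacing)
  w <- apply_transform(transform, w)
  idx <- world_to_index(w, target_volume$origin, target_volume$spacing)
  d <- dim(target_volume$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    inform(sprintf("transfer_voi: %d of %d voxels of '%s' left the target grid.",
                   n_dropped, length(inside), x$label))
  }
  idx <- unique(idx[inside, , drop = FALSE])
  if (nrow(idx) == 0) {
    abort(sprintf("VOI '%s' left the target field of view entirely.", x$label))
  }
  voi(idx, grid_id = target_volume$grid_id, label = x$label,
      spacing = target_volume$spacing, origin = target_volume$origin)
}

#' Mean uptake inside a VOI
#'
#' @param volume A [spect_volume()].
#' @param x A non-empty [voi()] on the same grid.
#' @return Arithmetic mean of the voxel values (counts/voxel).
#' @export
mean_uptake <- function(volume, x) {
  mean(voi_values(volume, x))
}

#' Peak uptake: mean counts in a 1-cm sphere around the hottest voxel
#'
#' Locates the maximum voxel inside the VOI (ties broken by lowest
#' lexicographic (z, y, x) index) and averages all voxels of the *grid* whose
#' centres lie within `sphere_diameter / 2` mm (Euclidean, world coordinates)
#' of that voxel's centre. The sphere may extend beyond the VOI but is clipped
#' at the grid boundary.
#'
#' @inheritParams mean_uptake
#' @param sphere_diameter Sphere diameter in mm; default 10 (1 cm).
#' @return Mean counts/voxel in the sphere neighbourhood.
#' @export
peak_uptake <- function(volume, x, sphere_diameter = 10) {
  vals <- voi_values(volume, x)
  r <- sphere_diameter / 2
  if (r < max(volume$spacing) / 2) {
    abort("Sphere radius must be at least half the largest voxel dimension.")
  }
  mx <- max(vals)
  centre_idx <- lex_first(x$indices[vals == mx, , drop = FALSE])
  centre <- index_to_world(matrix(centre_idx, ncol = 3),
                           volume$origin, volume$spacing)[1, ]
  d <- dim(volume$values)
  # bounding box of the sphere, clipped to the grid
  lo <- pmax(1L, centre_idx - ceiling(r / volume$spacing))
  hi <- pmin(d, centre_idx + ceiling(r / volume$spacing))
  box <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  w <- index_to_world(box, volume$origin, volume$spacing)
  dist2 <- rowSums(sweep(w, 2, centre, `-`)^2)
  inside <- dist2 <= r^2
  mean(volume$values[linear_index(box[inside, , drop = FALSE], d)])
}

#' Volume-weighted tumour-to-non-tumour ratio
#'
#' The tumour term is the volume-weighted average of per-lesion mean (or peak)
#' uptake over all target lesions of a lobe; the denominator is the mean
#' uptake of the normal-tissue VOI in the control lobe.
#'
#' @param lesion_means Per-lesion uptake values (counts/voxel).
#' @param lesion_volumes_ml Per-lesion VOI volumes in mL (the weights).
#' @param normal_mean Mean uptake in the normal-tissue VOI; must be positive.
#' @return The dimensionless T/N ratio.
#' @export
tn_ratio <- function(lesion_means, lesion_volumes_ml, normal_mean) {
  if (length(lesion_means) == 0 ||
        length(lesion_means) != length(lesion_volumes_ml)) {
    abort("`lesion_means` and `lesion_volumes_ml` must be non-empty and of equal length.")
  }
  if (any(lesion_volumes_ml <= 0)) {
    abort("Lesion volumes must be strictly positive.")
  }
  if (!is.finite(normal_mean) || normal_mean <= 0) {
    abort("`normal_mean` must be strictly positive to form a T/N ratio.")
  }
  sum(lesion_means * lesion_volumes_ml) / sum(lesion_volumes_ml) / normal_mean
}

#' Quantify one post-treatment cycle of one patient
#'
#' Transfers the baseline lesion and normal-tissue VOIs onto the cycle volume
#' through the (known) rigid transform, extracts per-lesion mean and peak
#' uptake plus the normal-tissue means, and assembles the T/N ratios of the
#' intra-arterially treated and the control lobe on both bases.
#'
#' @param cycle_volume The post-treatment emission [spect_volume()].
#' @param lesion_vois Named list of lesion [voi()]s segmented on the baseline
#'   grid.
#' @param lesion_lobes Character vector (`"left"`/`"right"`), one per lesion.
#' @param normal_voi Normal-tissue [voi()] in the control lobe, baseline grid.
#' @param ia_lobe Which lobe was treated intra-arterially: `"left"` or
#'   `"right"`.
#' @param transform Rigid transform from baseline world coordinates to the
#'   cycle volume's world coordinates; identity by default.
#' @param patient_id,cycle Identifiers copied into the output.
#' @return A tibble with one row per basis (`"mean"`, `"peak"`): columns
#'   `patient_id`, `cycle`, `basis`, `tn_ia`, `tn_control`. The per-lesion
#'   audit table (lesion, lobe, mean, peak, volume) is attached as attribute
#'   `"lesions"`.
#' @export
quantify_patient_cycle <- function(cycle_volume, lesion_vois, lesion_lobes,
                                   normal_voi, ia_lobe,
                                   transform = rigid_transform(),
                                   patient_id = "p1", cycle = 1L) {
  stopifnot(length(lesion_vois) == length(lesion_lobes))
  ia_lobe <- match.arg(ia_lobe, c("left", "right"))
  control_lobe <- setdiff(c("left", "right"), ia_lobe)
  for (lobe in c("left", "right")) {
    if (!any(lesion_lobes == lobe)) {
      abort(sprintf("No target lesion VOI supplied for the %s lobe.", lobe))
    }
  }
  moved <- lapply(lesion_vois, transfer_voi, transform = transform,
                  target_volume = cycle_volume)
  normal_moved <- transfer_voi(normal_voi, transform, cycle_volume)
  normal_mean <- mean_uptake(cycle_volume, normal_moved)
  if (normal_mean <= 0) {
    abort("Normal-tissue mean uptake is not positive; T/N undefined.")
  }
  lesions <- tibble(
    lesion = vapply(moved, function(v) v$label, character(1)),
    lobe = lesion_lobes,
    volume_ml = vapply(moved, voi_volume_ml, numeric(1)),
    mean_uptake = vapply(moved, function(v) mean_uptake(cycle_volume, v),
                         numeric(1)),
    peak_uptake = vapply(moved, function(v) peak_uptake(cycle_volume, v),
                         numeric(1)),
    normal_mean = normal_mean
  )
  one_basis <- function(basis) {
    col <- if (basis == "mean") lesions$mean_uptake else lesions$peak_uptake
    per_lobe <- function(lobe) {
      sel <- lesions$lobe == lobe
      tn_ratio(col[sel], lesions$volume_ml[sel], normal_mean)
    }
    tibble(patient_id = patient_id, cycle = as.integer(cycle), basis = basis,
           tn_ia = per_lobe(ia_lobe), tn_control = per_lobe(control_lobe))
  }
  out <- dplyr::bind_rows(one_basis("mean"), one_basis("peak"))
  attr(out, "lesions") <- lesions
  out
}
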