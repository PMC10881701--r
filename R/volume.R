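#' Emission image volumes and volumes of interest
#'
#' `spect_volume()` wraps a 3-D array of non-negative counts per voxel together
#' with its geometry: voxel spacing (mm), world origin (mm) and a grid
#' identifier. All grids are axis-aligned with no shear; the world coordinate
#' of voxel index `(i, j, k)` (1-based, as everywhere in R) is
#' `origin + (index - 1) * spacing`. On disk (NIfTI) voxel indices are 0-based;
#' [read_volume()] and [write_volume()] translate.
#'
#' @param values 3-D numeric array of counts per voxel; finite, `>= 0`.
#' @param spacing Voxel spacing in mm, length-3, strictly positive.
#' @param origin World coordinate (mm) of the centre of voxel `(1, 1, 1)`.
#' @param grid_id Character tag naming the grid; VOIs carry the same tag and
#'   operations refuse to mix grids.
#' @return An object of class `spect_volume`.
#' @seealso [voi()], [mean_uptake()], [peak_uptake()]
#' @export
spect_volume <- function(values, spacing, origin = c(0, 0, 0),
                         grid_id = "grid") {
  values <- unclass(values)
  attributes(values) <- list(dim = dim(values))
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array.")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and non-missing.")
  }
  if (any(values < 0)) {
    abort("`values` must be non-negative counts per voxel.")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (mm).")
  }
  if (length(origin) != 3L || anyNA(origin)) {
    abort("`origin` must be a length-3 numeric (mm).")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         grid_id = as.character(grid_id)),
    class = "spect_volume"
  )
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spect_volume '%s'> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    x$grid_id, d[1], d[2], d[3],
    paste(format(x$spacing), collapse = " x "),
    paste(format(x$origin), collapse = ", ")
  ))
  cat(sprintf("  counts/voxel: min %.3g, mean %.3g, max %.3g\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

#' Volume of interest on a voxel grid
#'
#' A VOI is a set of unique voxel indices (1-based, rows of an `n x 3` integer
#' matrix) on a named grid. Its physical volume in mL is derived from the voxel
#' count and spacing.
#'
#' @param indices Integer matrix with 3 columns (voxel indices, 1-based) or a
#'   3-column data frame.
#' @param grid_id Grid tag the indices refer to.
#' @param label Human-readable label (e.g. `"lesion_1"`, `"normal"`).
#' @param spacing Voxel spacing of the grid in mm (used for the mL volume).
#' @param origin World coordinate (mm) of voxel `(1, 1, 1)` of the grid the
#'   indices live on; required for VOI transfer between grids.
#' @param grid_dim Optional grid dimensions; when given, indices are checked
#'   against the bounds.
#' @return An object of class `voi`.
#' @export
voi <- function(indices, grid_id = "grid", label = "voi",
                spacing = c(1, 1, 1), origin = c(0, 0, 0), grid_dim = NULL) {
  indices <- as.matrix(indices)
  storage.mode(indices) <- "integer"
  if (ncol(indices) != 3L || nrow(indices) == 0L) {
    abort("`indices` must be a non-empty n x 3 matrix of voxel indices.")
  }
  if (anyNA(indices) || any(indices < 1L)) {
    abort("VOI indices must be positive (1-based) integers.")
  }
  indices <- unique(indices)
  dimnames(indices) <- NULL
  if (!is.null(grid_dim)) {
    if (any(indices[, 1] > grid_dim[1] | indices[, 2] > grid_dim[2] |
              indices[, 3] > grid_dim[3])) {
      abort("VOI indices fall outside the grid bounds.")
    }
  }
  structure(
    list(indices = indices, grid_id = as.character(grid_id),
         label = as.character(label), spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voi"
  )
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi '%s'> %d voxels on grid '%s' (%.2f mL)\n",
              x$label, nrow(x$indices), x$grid_id, voi_volume_ml(x)))
  invisible(x)
}

#' Physical volume of a VOI in millilitres
#'
#' @param x A [voi()].
#' @return Volume in mL (`voxel count * voxel volume / 1000`).
#' @export
voi_volume_ml <- function(x) {
  stopifnot(inherits(x, "voi"))
  nrow(x$indices) * prod(x$spacing) / 1000
}

#' World coordinates of voxel indices
#'
#' @param indices `n x 3` matrix of 1-based voxel indices.
#' @param origin,spacing Grid geometry in mm.
#' @return `n x 3` matrix of world coordinates (mm) of the voxel centres.
#' @export
index_to_world <- function(indices, origin, spacing) {
  indices <- as.matrix(indices)
  sweep(sweep(indices - 1, 2, spacing, `*`), 2, origin, `+`)
}

#' Nearest voxel indices of world coordinates
#'
#' @param world `n x 3` matrix of world coordinates (mm).
#' @inheritParams index_to_world
#' @return `n x 3` integer matrix of 1-based voxel indices (unclipped; callers
#'   decide how to treat out-of-grid results).
#' @export
world_to_index <- function(world, origin, spacing) {
  world <- as.matrix(world)
  idx <- round(sweep(sweep(world, 2, origin, `-`), 2, spacing, `/`)) + 1
  storage.mode(idx) <- "integer"
  idx
}

linear_index <- function(indices, d) {
  (indices[, 1] - 1L) + (indices[, 2] - 1L) * d[1] +
    (indices[, 3] - 1L) * d[1] * d[2] + 1L
}

voi_values <- function(volume, x) {
  check_same_grid(volume, x)
  volume$values[linear_index(x$indices, dim(volume$values))]
}

check_same_grid <- function(volume, voi) {
  if (!identical(volume$grid_id, voi$grid_id)) {
    abort(sprintf("VOI '%s' lives on grid '%s' but the volume is grid '%s'.",
                  voi$label, voi$grid_id, volume$grid_id))
  }
  d <- dim(volume$values)
  if (any(voi$indices[, 1] > d[1] | voi$indices[, 2] > d[2] |
            voi$indices[, 3] > d[3])) {
    abort("VOI indices fall outside the volume grid.")
  }
  invisible(TRUE)
}

#' Rigid transform between two world coordinate frames
#'
#' Maps source-grid world coordinates to target-grid world coordinates as
#' `x' = R x + t`. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
        abs(det(rotation) - 1) > 1e-8) {
    abort("`rotation` must be a 3 x 3 orthonormal matrix with determinant +1.")
  }
  if (length(translation) != 3L || anyNA(translation)) {
    abort("`translation` must be a length-3 numeric (mm).")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%s) mm\n",
              ang, paste(format(x$translation, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' @param transform A [rigid_transform()].
#' @param points `n x 3` matrix of world coordinates.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Draw a small random rigid transform
#'
#' Rotation about a uniformly random axis by an angle uniform on
#' `[0, max_angle_deg]`, translation uniform in the cube
#' `[-max_translation, max_translation]^3`.
#'
#' @param max_translation Maximum per-axis translation in mm.
#' @param max_angle_deg Maximum rotation angle in degrees.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_translation = 4, max_angle_deg = 3) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, 0, max_angle_deg * pi / 180)
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  rot <- diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
  # re-orthonormalize against accumulated floating error
  sv <- svd(rot)
  rot <- sv$u %*% t(sv$v)
  rigid_transform(rot, runif(3, -max_translation, max_translation))
}

#' Read and write emission volumes as NIfTI
#'
#' Geometry is stored in the sform (diagonal spacing plus origin offset);
#' voxel indices on disk are 0-based per the NIfTI convention.
#'
#' @param volume A [spect_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns a
#'   [spect_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "spect_volume"))
  img <- RNifti::asNifti(volume$values)
  m <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param grid_id Grid tag to assign to the volume read from `path`.
#' @rdname write_volume
#' @export
read_volume <- function(path, grid_id = basename(path)) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  spacing <- diag(x[1:3, 1:3])
  if (max(abs(x[1:3, 1:3] - diag(spacing))) > 1e-6) {
    abort("Only axis-aligned volumes without rotation/shear are supported.")
  }
  spect_volume(as.array(img), spacing = spacing, origin = x[1:3, 4],
               grid_id = grid_id)
}

#' Convert VOIs to an integer label map and back
#'
#' `vois_to_labelmap()` rasterizes a list of VOIs into an integer volume
#' (labels 1, 2, ... in list order; later VOIs overwrite earlier ones where
#' they overlap). `labelmap_to_vois()` inverts it.
#'
#' @param vois List of [voi()] objects on the same grid.
#' @param reference A [spect_volume()] providing grid geometry.
#' @return An integer-valued [spect_volume()], or a named list of VOIs.
#' @export
vois_to_labelmap <- function(vois, reference) {
  lab <- array(0L, dim(reference$values))
  for (i in seq_along(vois)) {
    check_same_grid(reference, vois[[i]])
    lab[linear_index(vois[[i]]$indices, dim(lab))] <- i
  }
  spect_volume(lab, spacing = reference$spacing, origin = reference$origin,
               grid_id = reference$grid_id)
}

#' @param labelmap An integer-valued [spect_volume()] of VOI labels.
#' @param labels Optional character names for the positive labels.
#' @rdname vois_to_labelmap
#' @export
labelmap_to_vois <- function(labelmap, labels = NULL) {
  vals <- sort(unique(labelmap$values[labelmap$values > 0]))
  out <- lapply(vals, function(v) {
    voi(which(labelmap$values == v, arr.ind = TRUE),
        grid_id = labelmap$grid_id,
        label = if (is.null(labels)) paste0("label_", v) else labels[[v]],
        spacing = labelmap$spacing, origin = labelmap$origin)
  })
  names(out) <- vapply(out, function(v) v$label, character(1))
  out
}
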