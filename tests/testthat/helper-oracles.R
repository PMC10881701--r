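# Brute-force reference implementations, independent of the package's
# algorithms, used as oracles for the quantification chain.

# threshold + flood fill by repeated mask dilation (array algebra, no graph)
oracle_segment <- function(values, rough_mask, threshold = 0.42) {
  d <- dim(values)
  mx <- max(values[rough_mask])
  keep <- rough_mask & (values >= threshold * mx)
  # seed: lowest lexicographic (z, y, x) among maxima inside the rough VOI
  hits <- which(rough_mask & values == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 3], hits[, 2], hits[, 1]), , drop = FALSE]
  comp <- array(FALSE, d)
  comp[hits[1, 1], hits[1, 2], hits[1, 3]] <- TRUE
  repeat {
    grown <- comp
    idx <- which(comp, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        p <- idx[r, ] + c(dx, dy, dz)
        if (all(p >= 1) && all(p <= d) && keep[p[1], p[2], p[3]]) {
          grown[p[1], p[2], p[3]] <- TRUE
        }
      }
    }
    if (identical(grown, comp)) break
    comp <- grown
  }
  which(comp, arr.ind = TRUE)
}

# peak: scan every voxel of the grid for sphere membership
oracle_peak <- function(values, voi_idx, spacing, origin = c(0, 0, 0),
                        diameter = 10) {
  d <- dim(values)
  vals <- values[cbind(voi_idx[, 1], voi_idx[, 2], voi_idx[, 3])]
  mx <- max(vals)
  tied <- voi_idx[vals == mx, , drop = FALSE]
  tied <- tied[order(tied[, 3], tied[, 2], tied[, 1]), , drop = FALSE]
  centre <- origin + (tied[1, ] - 1) * spacing
  acc <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- origin + (c(i, j, k) - 1) * spacing
    if (sum((w - centre)^2) <= (diameter / 2)^2) {
      acc <- c(acc, values[i, j, k])
    }
  }
  mean(acc)
}

# transfer: map every source voxel centre individually
oracle_transfer <- function(voi_idx, spacing_src, origin_src, rot, tr,
                            spacing_tgt, origin_tgt, dim_tgt) {
  out <- matrix(integer(0), 0, 3)
  for (r in seq_len(nrow(voi_idx))) {
    w <- origin_src + (voi_idx[r, ] - 1) * spacing_src
    w2 <- as.vector(rot %*% w) + tr
    p <- round((w2 - origin_tgt) / spacing_tgt) + 1
    if (all(p >= 1) && all(p <= dim_tgt)) out <- rbind(out, p)
  }
  unique(out)
}

sort_idx <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# a random test volume with a hot blob, for property-style checks
random_blob_volume <- function(d = c(8, 8, 8), spacing = c(4, 4, 4)) {
  vals <- array(runif(prod(d), 0, 1), d)
  c0 <- runif(3, 2, d - 1)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dist <- sqrt(sum((c(i, j, k) - c0)^2))
    vals[i, j, k] <- vals[i, j, k] + 10 * exp(-dist^2 / 4)
  }
  spect_volume(vals, spacing = spacing, grid_id = "g")
}
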