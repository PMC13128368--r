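# Independent brute-force oracles, kept deliberately naive (full scans,
# explicit loops) so they share no code path with the implementation.

# L-inf distance from each point (rows, mm) to the nearest TRUE raster voxel
# centre, by full scan over the raster.
bf_linf_dist <- function(volume, mask, pts) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) return(rep(Inf, nrow(pts)))
  ctr <- index_to_mm(volume, idx)
  apply(pts, 1, function(p) {
    min(pmax(abs(ctr[, 1] - p[1]),
             pmax(abs(ctr[, 2] - p[2]), abs(ctr[, 3] - p[3]))))
  })
}

# Which candidate voxels the Chebyshev rule should exclude (no raster-edge
# handling: callers use masks with clear margins).
bf_chebyshev_keep <- function(grid, region, ventricle, d_boundary_um,
                              d_ventricle_um, region_labels = 1L) {
  pts <- voxel_centers(grid, grid$candidate)
  ext <- !(region$labels %in% region_labels)
  dim(ext) <- dim(region$labels)
  eps <- 1e-9  # exact-equality distances are kept (strict < rule)
  keep <- bf_linf_dist(region, ext, pts) >= d_boundary_um / 1000 - eps
  if (!is.null(ventricle)) {
    vm <- ventricle$labels != 0L
    dim(vm) <- dim(ventricle$labels)
    keep <- keep &
      bf_linf_dist(ventricle, vm, pts) >= d_ventricle_um / 1000 - eps
  }
  keep
}

# Per-cell floor-division voxel assignment
bf_voxel_counts <- function(cells, grid) {
  counts <- array(0L, dim = grid$shape)
  edge <- grid$edge_um / 1000
  for (r in seq_len(nrow(cells))) {
    i <- floor((cells$ap_mm[r] - grid$origin_mm[1]) / edge)
    j <- floor((cells$ml_mm[r] - grid$origin_mm[2]) / edge)
    k <- floor((cells$dv_mm[r] - grid$origin_mm[3]) / edge)
    if (i >= 0 && i < grid$shape[1] && j >= 0 && j < grid$shape[2] &&
        k >= 0 && k < grid$shape[3])
      counts[i + 1, j + 1, k + 1] <- counts[i + 1, j + 1, k + 1] + 1L
  }
  counts
}

# Direct triple-sum masked Gaussian convolution
bf_smooth <- function(vals, included, sigma) {
  r <- ceiling(3 * sigma)
  dm <- dim(vals)
  out <- array(NA_real_, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (!included[i, j, k]) next
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) next
      if (!included[ii, jj, kk]) next
      w <- exp(-(di^2 + dj^2 + dk^2) / (2 * sigma^2))
      num <- num + w * vals[ii, jj, kk]
      den <- den + w
    }
    out[i, j, k] <- num / den
  }
  out
}

# Per-point parcel lookup
bf_assign <- function(cells, parc) {
  vol <- parc$volume
  sp <- vol$spacing_um / 1000
  nm <- names(vol$label_map)
  out <- character(nrow(cells))
  dims <- dim(vol$labels)
  for (r in seq_len(nrow(cells))) {
    p <- c(cells$ap_mm[r], cells$ml_mm[r], cells$dv_mm[r])
    u <- vol$frame$axis_signs * (p - vol$frame$origin_mm) / sp
    ijk <- floor(u + 0.5)
    if (any(ijk < 0) || any(ijk >= dims)) { out[r] <- "unassigned"; next }
    lab <- vol$labels[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
    hit <- match(lab, unname(vol$label_map))
    out[r] <- if (is.na(hit)) "unassigned" else nm[hit]
  }
  out
}

# Gaussian log-likelihood of the one-way random-intercept model, via the
# dense marginal covariance (oracle for the lme4-backed engine).
ri_loglik <- function(y, X, beta, sigma_u2, sigma_e2, group) {
  g <- as.integer(factor(group))
  Z <- outer(g, sort(unique(g)), "==") * 1
  V <- sigma_e2 * diag(length(y)) + sigma_u2 * (Z %*% t(Z))
  r <- y - X %*% beta
  -0.5 * (length(y) * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(r) %*% solve(V) %*% r))
}
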