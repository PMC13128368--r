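#' Per-voxel cell counts on the analysis grid
#'
#' Assigns each cell to exactly one grid voxel by half-open intervals
#' \code{[lo, hi)} (a cell exactly on a shared face goes to the higher-index
#' voxel), so total counts are conserved.
#'
#' @param cells a \code{cell_table}.
#' @param grid a \code{voxel_grid}.
#' @return integer 3D array of counts over the full grid, with attributes
#'   \code{n_outside_grid} (cells beyond the grid bounding box),
#'   \code{n_outside_included} (cells in voxels not currently included) and
#'   \code{n_included} (cells landing in included voxels).
#' @export
voxel_counts <- function(cells, grid) {
  counts <- array(0L, dim = grid$shape)
  gi <- grid_index(grid, as.matrix(cells[, c("ap_mm", "ml_mm", "dv_mm")]))
  inside <- !is.na(gi[, 1])
  if (any(inside)) {
    lin <- 1L + gi[inside, 1] +
      grid$shape[1] * (gi[inside, 2] + grid$shape[2] * gi[inside, 3])
    tab <- tabulate(lin, nbins = prod(grid$shape))
    counts[] <- tab
  }
  n_out_grid <- sum(!inside)
  n_in_incl <- sum(counts[grid$included])
  attr(counts, "n_outside_grid") <- n_out_grid
  attr(counts, "n_outside_included") <- nrow(cells) - n_out_grid - n_in_incl
  attr(counts, "n_included") <- n_in_incl
  counts
}

#' Hemisphere-level bootstrap density map
#'
#' Hemispheres are the independent sampling unit: each of \code{n_boot}
#' replicates draws \code{n} hemispheres with replacement from the \code{n}
#' available and computes per-voxel density as summed counts over the drawn
#' hemispheres divided by (n_drawn x voxel volume), i.e. a per-hemisphere
#' density in cells/mm^3. The map's \code{mean_density} and \code{se_density}
#' are the mean and standard deviation of the replicate densities. A
#' \code{"cell"} resampling unit (cells within hemisphere resampled,
#' hemispheres fixed) is available for sensitivity analyses.
#'
#' @param cells_by_hemisphere named list of \code{cell_table}s, one per
#'   hemisphere, all of one subtype.
#' @param grid a \code{voxel_grid} (inclusion mask already applied).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional RNG seed; the seed fully determines the output.
#' @param unit resampling unit, \code{"hemisphere"} (default) or \code{"cell"}.
#' @return an object of class \code{density_map}: 3D arrays
#'   \code{mean_density} and \code{se_density} (NA outside included voxels),
#'   plus \code{subtype}, \code{n_hemispheres}, \code{n_boot}, \code{grid}.
#' @export
bootstrap_density <- function(cells_by_hemisphere, grid, n_boot = 1000L,
                              seed = NULL, unit = c("hemisphere", "cell")) {
  unit <- match.arg(unit)
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  H <- length(cells_by_hemisphere)
  if (H < 1L) stopf("need at least one hemisphere")
  subtype <- unique(vapply(cells_by_hemisphere,
                           function(d) d$subtype[1] %||% NA_character_,
                           character(1)))
  subtype <- subtype[!is.na(subtype)]
  if (length(subtype) > 1L) stopf("all hemispheres must share one subtype")
  if (!is.null(seed)) set.seed(seed)

  incl <- which(grid$included)
  V <- length(incl)
  vol <- grid$voxel_volume_mm3
  Cmat <- matrix(0, nrow = H, ncol = V)
  for (h in seq_len(H)) {
    cnt <- voxel_counts(cells_by_hemisphere[[h]], grid)
    Cmat[h, ] <- cnt[incl]
  }

  if (unit == "hemisphere") {
    draws <- matrix(sample.int(H, H * n_boot, replace = TRUE), nrow = n_boot)
    W <- matrix(0L, nrow = n_boot, ncol = H)
    for (r in seq_len(n_boot)) W[r, ] <- tabulate(draws[r, ], nbins = H)
    dens <- (W %*% Cmat) / (H * vol)
  } else {
    dens <- matrix(0, nrow = n_boot, ncol = V)
    sizes <- vapply(cells_by_hemisphere, nrow, integer(1))
    for (r in seq_len(n_boot)) {
      tot <- numeric(V)
      for (h in seq_len(H)) {
        nh <- sizes[h]
        if (nh == 0L) next
        ridx <- sample.int(nh, nh, replace = TRUE)
        cnt <- voxel_counts(cells_by_hemisphere[[h]][ridx, , drop = FALSE], grid)
        tot <- tot + cnt[incl]
      }
      dens[r, ] <- tot / (H * vol)
    }
  }

  m <- colMeans(dens)
  s <- sqrt(colSums(sweep(dens, 2, m, "-")^2) / max(1L, n_boot - 1L))
  mean_density <- se_density <- array(NA_real_, dim = grid$shape)
  mean_density[incl] <- m
  se_density[incl] <- s
  structure(list(subtype = if (length(subtype)) subtype else NA_character_,
                 grid = grid, mean_density = mean_density,
                 se_density = se_density, n_hemispheres = H,
                 n_boot = as.integer(n_boot)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  v <- x$mean_density[x$grid$included]
  cat(sprintf(
    "<density_map> %s: %d voxels, %d hemispheres, %d bootstraps; mean %.1f cells/mm^3 (range %.1f-%.1f)\n",
    x$subtype, length(v), x$n_hemispheres, x$n_boot, mean(v), min(v), max(v)))
  invisible(x)
}

#' Mask-aware Gaussian smoothing of a density map
#'
#' Truncated Gaussian kernel (radius 3 sigma, sigma in voxel units) applied
#' with mask renormalization: each output voxel is the kernel-weighted mean
#' over included voxels only, weights renormalized to sum to one within the
#' mask. Constants are preserved exactly; with full inclusion this equals
#' standard discrete Gaussian convolution. Applied to \code{mean_density}
#' after bootstrap aggregation; \code{se_density} is left untouched.
#'
#' @param map a \code{density_map}.
#' @param sigma_voxel kernel sigma in voxel units (default 0.5, i.e. 75 um on
#'   the 150 um grid); \code{0} is the identity.
#' @return the smoothed \code{density_map}.
#' @export
smooth_density <- function(map, sigma_voxel = 0.5) {
  if (sigma_voxel < 0) stopf("sigma_voxel must be non-negative")
  if (sigma_voxel == 0) return(map)
  grid <- map$grid
  r <- as.integer(ceiling(3 * sigma_voxel))
  offs <- -r:r
  vals <- map$mean_density
  vals[!grid$included] <- 0
  m <- grid$included * 1
  num <- array(0, dim = grid$shape)
  den <- array(0, dim = grid$shape)
  for (dx in offs) for (dy in offs) for (dz in offs) {
    d2 <- dx^2 + dy^2 + dz^2
    if (max(abs(c(dx, dy, dz))) > r) next
    w <- exp(-d2 / (2 * sigma_voxel^2))
    num <- num + w * shift_array(vals, c(dx, dy, dz))
    den <- den + w * shift_array(m, c(dx, dy, dz))
  }
  out <- array(NA_real_, dim = grid$shape)
  ok <- grid$included & den > 0
  out[ok] <- num[ok] / den[ok]
  map$mean_density <- out
  map
}

# Shift a 3D array by integer offsets, zero-padding
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(0, dim = dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      src[[k]] <- 1:(dm[k] - d[k]); dst[[k]] <- (1 + d[k]):dm[k]
    } else {
      if (-d[k] >= dm[k]) return(out)
      src[[k]] <- (1 - d[k]):dm[k]; dst[[k]] <- 1:(dm[k] + d[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Pooled quantile density binning
#'
#' Pools the included-voxel densities of all maps and computes the
#' \code{k/n_bins} empirical quantiles (k = 1..n_bins, linear interpolation,
#' type 7) as shared thresholds; each voxel of each map receives the index of
#' the first threshold at or above its density, with tied thresholds
#' collapsing to the highest index (so a degenerate all-equal pool lands in
#' the top bin).
#'
#' @param maps list of \code{density_map}s on a shared grid.
#' @param n_bins number of thresholds/bins (default 15, the published
#'   binning).
#' @return object of class \code{quantile_binning}: \code{thresholds}
#'   (non-decreasing n_bins-vector) and \code{bin_index} (list of integer 3D
#'   arrays, one per map, NA outside included voxels).
#' @export
pooled_quantile_bins <- function(maps, n_bins = 15L) {
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  if (length(maps) < 1L) stopf("need at least one map")
  grid <- maps[[1]]$grid
  incl <- which(grid$included)
  pooled <- unlist(lapply(maps, function(m) m$mean_density[incl]))
  thresholds <- stats::quantile(pooled, probs = seq_len(n_bins) / n_bins,
                                type = 7, names = FALSE)
  # highest index among tied threshold values
  tie_top <- vapply(seq_len(n_bins),
                    function(k) max(which(thresholds == thresholds[k])),
                    integer(1))
  bin_of <- function(v) {
    j <- findInterval(v, thresholds, left.open = TRUE) + 1L
    j[j > n_bins] <- n_bins
    tie_top[j]
  }
  bins <- lapply(maps, function(m) {
    b <- array(NA_integer_, dim = grid$shape)
    b[incl] <- bin_of(m$mean_density[incl])
    b
  })
  names(bins) <- vapply(maps, function(m) m$subtype, character(1))
  structure(list(thresholds = thresholds, bin_index = bins,
                 n_bins = as.integer(n_bins)),
            class = "quantile_binning")
}

#' Voxel-wise subtype predominance map
#'
#' Assigns each included voxel to the subtype with the highest mean density
#' there. Exact ties are broken by the order of \code{maps} (SST, PV, TH in
#' the standard pipeline) and counted. A qualitative summary of relative
#' enrichment, not exclusivity.
#'
#' @param maps named list (>= 2) of \code{density_map}s sharing a grid and
#'   inclusion mask.
#' @return object of class \code{predominance_map}: \code{labels} (integer 3D
#'   array of indices into \code{subtypes}, NA outside the mask),
#'   \code{subtypes}, and \code{n_ties}.
#' @export
predominance <- function(maps) {
  if (length(maps) < 2L) stopf("need at least two maps")
  grid <- maps[[1]]$grid
  incl <- which(grid$included)
  for (m in maps[-1]) {
    if (!identical(which(m$grid$included), incl))
      stopf("all maps must share grid and inclusion mask")
  }
  dmat <- vapply(maps, function(m) m$mean_density[incl],
                 numeric(length(incl)))
  win <- apply(dmat, 1, which.max)
  mx <- dmat[cbind(seq_len(nrow(dmat)), win)]
  n_ties <- sum(rowSums(dmat == mx) > 1L)
  labels <- array(NA_integer_, dim = grid$shape)
  labels[incl] <- win
  subtypes <- names(maps) %||% vapply(maps, function(m) m$subtype, character(1))
  if (is.null(names(maps)))
    names(maps) <- subtypes
  structure(list(labels = labels, subtypes = subtypes,
                 n_ties = as.integer(n_ties), grid = grid),
            class = "predominance_map")
}

#' @export
print.predominance_map <- function(x, ...) {
  tab <- table(factor(x$labels[x$grid$included], levels = seq_along(x$subtypes),
                      labels = x$subtypes))
  cat("<predominance_map>", sum(tab), "voxels;", x$n_ties, "ties\n")
  print(tab)
  invisible(x)
}
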