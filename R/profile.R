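#' Collapse densities to a one-dimensional axis profile
#'
#' For each hemisphere and each 150 um slab (grid plane) along the chosen
#' anatomical axis, density = cells landing in included voxels of the slab
#' divided by the included volume of the slab. Planes with zero included
#' voxels are dropped for all hemispheres. Plane-wise bootstrap mean and SE
#' (hemisphere resampling) are attached when \code{n_boot > 0}.
#'
#' @param cells_by_hemisphere named list of per-hemisphere \code{cell_table}s
#'   (one subtype).
#' @param grid a \code{voxel_grid} with exclusions applied.
#' @param axis \code{"AP"}, \code{"ML"} or \code{"DV"}.
#' @param n_boot bootstrap replicates per plane (default 1000; 0 skips).
#' @param seed optional RNG seed for the bootstrap.
#' @return object of class \code{axis_profile}: \code{axis},
#'   \code{plane_centers_mm}, \code{plane_edges_mm}, \code{density}
#'   (hemispheres x planes matrix of raw densities, cells/mm^3),
#'   \code{included_volume_mm3} (per plane), \code{boot_mean},
#'   \code{boot_se}, \code{sex} (named by hemisphere), \code{subtype}.
#' @export
collapse_axis <- function(cells_by_hemisphere, grid, axis = c("AP", "ML", "DV"),
                          n_boot = 1000L, seed = NULL) {
  ax <- axis_index(match.arg(axis))
  H <- length(cells_by_hemisphere)
  if (H < 1L) stopf("need at least one hemisphere")
  P_all <- grid$shape[ax]
  vox_per_plane <- apply(grid$included, ax, sum)
  retained <- which(vox_per_plane > 0L)
  if (length(retained) == 0L) stopf("no plane has an included voxel")
  vol <- vox_per_plane[retained] * grid$voxel_volume_mm3

  D <- matrix(0, nrow = H, ncol = length(retained),
              dimnames = list(names(cells_by_hemisphere), NULL))
  for (h in seq_len(H)) {
    cnt <- voxel_counts(cells_by_hemisphere[[h]], grid)
    cnt[!grid$included] <- 0L
    plane_counts <- apply(cnt, ax, sum)
    D[h, ] <- plane_counts[retained] / vol
  }

  edge <- grid$edge_um / 1000
  centers <- grid$origin_mm[ax] + (retained - 1L + 0.5) * edge
  edges <- grid$origin_mm[ax] + c(retained - 1L, max(retained)) * edge

  boot_mean <- boot_se <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    draws <- matrix(sample.int(H, H * n_boot, replace = TRUE), nrow = n_boot)
    W <- matrix(0L, nrow = n_boot, ncol = H)
    for (r in seq_len(n_boot)) W[r, ] <- tabulate(draws[r, ], nbins = H)
    reps <- (W %*% D) / H
    boot_mean <- colMeans(reps)
    boot_se <- sqrt(colSums(sweep(reps, 2, boot_mean, "-")^2) /
                      max(1L, n_boot - 1L))
  }

  subtype <- unique(vapply(cells_by_hemisphere,
                           function(d) d$subtype[1] %||% NA_character_,
                           character(1)))
  structure(list(axis = match.arg(axis), plane_centers_mm = centers,
                 plane_edges_mm = edges, density = D,
                 included_volume_mm3 = vol,
                 boot_mean = boot_mean, boot_se = boot_se,
                 sex = hemisphere_sex(cells_by_hemisphere),
                 subtype = subtype[!is.na(subtype)][1] %||% NA_character_,
                 n_boot = as.integer(n_boot)),
            class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("<axis_profile> %s (%s): %d hemispheres x %d planes\n",
              x$axis, x$subtype, nrow(x$density), ncol(x$density)))
  invisible(x)
}

#' Long-format view of an axis profile
#' @param profile an \code{axis_profile}.
#' @return data.frame with hemisphere_id, sex, axis, plane_center_mm, density.
#' @export
profile_long <- function(profile) {
  H <- nrow(profile$density); P <- ncol(profile$density)
  data.frame(hemisphere_id = rep(rownames(profile$density), times = P),
             sex = rep(unname(profile$sex), times = P),
             axis = profile$axis,
             plane_center_mm = rep(profile$plane_centers_mm, each = H),
             density = as.vector(profile$density),
             stringsAsFactors = FALSE)
}

#' @export
plot.axis_profile <- function(x, ...) {
  long <- profile_long(x)
  plot(long$plane_center_mm, long$density, pch = 16,
       col = grDevices::adjustcolor("grey40", 0.5),
       xlab = sprintf("%s coordinate (mm)", x$axis),
       ylab = "density (cells/mm^3)",
       main = sprintf("%s axis profile (%s)", x$axis, x$subtype), ...)
  if (!is.null(x$boot_mean)) {
    graphics::lines(x$plane_centers_mm, x$boot_mean, lwd = 2, col = "firebrick")
    graphics::arrows(x$plane_centers_mm, x$boot_mean - x$boot_se,
                     x$plane_centers_mm, x$boot_mean + x$boot_se,
                     angle = 90, code = 3, length = 0.02, col = "firebrick")
  }
  invisible(x)
}
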