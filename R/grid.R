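#' Build the cubic analysis voxel grid over a region mask
#'
#' Lays an isotropic lattice of cubic voxels (default edge 150 um, the
#' published analysis scale) over the bounding box of the region mask, with
#' the grid origin anchored at the bounding-box minimum corner snapped to the
#' raster. A grid voxel is candidate-included iff at least one region-raster
#' voxel of a listed label has its centre inside it (half-open intervals).
#'
#' @param region a \code{\link{label_volume}}.
#' @param region_labels integer label codes defining the region.
#' @param edge_um grid voxel edge, micrometres.
#' @return an object of class \code{voxel_grid}: fields \code{edge_um},
#'   \code{origin_mm} (corner of voxel (0,0,0)), \code{shape},
#'   \code{included} (logical 3D array), \code{candidate} (inclusion before
#'   any distance exclusion), \code{voxel_volume_mm3}, \code{frame},
#'   \code{region_labels}.
#' @export
build_voxel_grid <- function(region, region_labels, edge_um = 150) {
  if (length(region_labels) == 0L) stopf("region_labels must be non-empty")
  if (!is.numeric(edge_um) || edge_um <= 0) stopf("edge_um must be positive")
  if (region$spacing_um > edge_um)
    stopf("region raster spacing (%g um) is coarser than edge_um (%g um)",
          region$spacing_um, edge_um)
  mask <- region$labels %in% region_labels
  dim(mask) <- dim(region$labels)
  if (!any(mask)) stopf("no raster voxel carries a listed region label")

  idx <- which(mask, arr.ind = TRUE) - 1L
  centers <- index_to_mm(region, idx)
  sp <- region$spacing_um / 1000
  edge <- edge_um / 1000
  lo <- apply(centers, 2, min) - sp / 2   # raster-snapped bbox corner
  hi <- apply(centers, 2, max) + sp / 2
  shape <- as.integer(ceiling((hi - lo) / edge - 1e-9))
  shape <- pmax(shape, 1L)

  gi <- floor(sweep(centers, 2, lo, "-") / edge)
  gi <- pmin(pmax(gi, 0L), matrix(rep(shape - 1L, each = nrow(gi)), ncol = 3L))
  storage.mode(gi) <- "integer"
  included <- array(FALSE, dim = shape)
  included[gi + 1L] <- TRUE

  structure(list(edge_um = as.numeric(edge_um), origin_mm = lo, shape = shape,
                 included = included, candidate = included,
                 voxel_volume_mm3 = (edge_um / 1000)^3,
                 frame = region$frame, region_labels = region_labels),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels of %g um; %d included (%.3f mm^3)\n",
              paste(x$shape, collapse = " x "), x$edge_um, sum(x$included),
              sum(x$included) * x$voxel_volume_mm3))
  invisible(x)
}

#' Centres of grid voxels, in frame mm
#'
#' @param grid a \code{voxel_grid}.
#' @param which logical 3D array selecting voxels (default: included voxels).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(grid, which = grid$included) {
  idx <- base::which(which, arr.ind = TRUE) - 1L
  sweep((idx + 0.5) * (grid$edge_um / 1000), 2, grid$origin_mm, "+")
}

# Zero-based grid voxel index of each mm coordinate (NA outside bbox)
grid_index <- function(grid, coords_mm) {
  gi <- floor(sweep(rbind_vec(coords_mm), 2, grid$origin_mm, "-") /
                (grid$edge_um / 1000))
  inside <- gi[, 1] >= 0 & gi[, 1] < grid$shape[1] &
            gi[, 2] >= 0 & gi[, 2] < grid$shape[2] &
            gi[, 3] >= 0 & gi[, 3] < grid$shape[3]
  gi[!inside, ] <- NA_integer_
  storage.mode(gi) <- "integer"
  gi
}

#' Exclude grid voxels near the region boundary or a ventricle
#'
#' Applies the Chebyshev (L-infinity) distance exclusion: a candidate voxel is
#' dropped iff the L-inf distance from its centre to the nearest
#' region-exterior raster voxel centre is below \code{d_boundary_um}, or to
#' the nearest ventricle-labelled raster voxel centre is below
#' \code{d_ventricle_um}. Distances are voxel-centre-to-voxel-centre at the
#' label raster's native resolution; raster positions beyond the raster
#' extent count as exterior.
#'
#' @param grid a \code{voxel_grid} built from \code{region}.
#' @param region the region \code{label_volume} the grid was built from.
#' @param ventricle optional ventricle \code{label_volume} on the same frame
#'   and raster spacing; if \code{NULL} the ventricle exclusion is skipped
#'   with a warning.
#' @param d_boundary_um boundary exclusion distance, um (default 50).
#' @param d_ventricle_um ventricle exclusion distance, um (default 175).
#' @param ventricle_labels labels marking ventricle voxels (default: all
#'   nonzero).
#' @return the grid with updated \code{included}.
#' @export
chebyshev_exclude <- function(grid, region, ventricle = NULL,
                              d_boundary_um = 50, d_ventricle_um = 175,
                              ventricle_labels = NULL) {
  if (d_boundary_um < 0 || d_ventricle_um < 0)
    stopf("exclusion distances must be non-negative")
  if (!frames_equal(grid$frame, region$frame))
    stopf("grid and region are on different frames")
  exterior <- !(region$labels %in% grid$region_labels)
  dim(exterior) <- dim(region$labels)

  vmask <- NULL
  if (!is.null(ventricle)) {
    if (!frames_equal(region$frame, ventricle$frame) ||
        abs(region$spacing_um - ventricle$spacing_um) > 1e-9)
      stopf("ventricle volume is on a different frame or raster spacing")
    vmask <- if (is.null(ventricle_labels)) ventricle$labels != 0L
             else ventricle$labels %in% ventricle_labels
    dim(vmask) <- dim(ventricle$labels)
  } else {
    warnf("no ventricle volume supplied; ventricle exclusion skipped")
  }

  centers <- voxel_centers(grid, grid$included)
  keep <- !linf_hit(region, exterior, centers, d_boundary_um / 1000,
                    outside_counts = TRUE)
  if (!is.null(vmask)) {
    keep <- keep & !linf_hit(ventricle, vmask, centers, d_ventricle_um / 1000,
                             outside_counts = FALSE)
  }
  included <- array(FALSE, dim = grid$shape)
  included[which(grid$included)[keep]] <- TRUE
  grid$included <- included
  grid
}

# For each point (rows of pts, mm): is there a TRUE raster voxel centre at
# L-inf distance strictly below d_mm?  outside_counts: positions beyond the
# raster extent count as hits (used for the region-exterior test).
linf_hit <- function(volume, mask, pts, d_mm, outside_counts = FALSE) {
  n <- nrow(pts)
  hit <- logical(n)
  if (d_mm <= 0) return(hit)
  sp <- volume$spacing_um / 1000
  fr <- volume$frame
  dims <- dim(mask)
  r <- d_mm / sp
  # continuous raster index of each point, per axis
  u <- sweep(sweep(pts, 2, fr$origin_mm, "-"), 2, fr$axis_signs / sp, "*")
  jlo <- ceiling(u - r + 1e-9)
  jhi <- floor(u + r - 1e-9)
  for (i in seq_len(n)) {
    lo <- jlo[i, ]; hi <- jhi[i, ]
    if (any(lo > hi)) next
    clipped <- any(lo < 0) || any(hi > dims - 1L)
    if (clipped && outside_counts) { hit[i] <- TRUE; next }
    lo <- pmax(lo, 0); hi <- pmin(hi, dims - 1L)
    if (any(lo > hi)) next
    sub <- mask[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L]
    hit[i] <- any(sub)
  }
  hit
}
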