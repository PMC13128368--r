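#' Configuration for the synthetic reference space and cell generator
#'
#' The generator emulates the spatial and statistical structure of the real
#' study: an ellipsoidal one-hemisphere region in a 50 um reference raster
#' with a thin ventricle sheet on its medial face and four parcels
#' (DMCP/LCP/TCP/aVMCP); cell point patterns drawn per hemisphere from an
#' inhomogeneous Poisson process whose intensity (cells/mm^3) is linear along
#' the anatomical axes, with Gaussian hemisphere random intercepts, Gaussian
#' per-coronal-section intensity noise (the section-level detection and
#' registration variability that dominates residual variation at the plane
#' level), optional sex effects, and truncation of the intensity at zero.
#' Slope defaults are the study-scale axis gradients (female slope plus male
#' offset where sex interactions are modelled); left-side hemispheres are
#' generated mirrored (negative ML) so the midline-mirroring stage is
#' exercised. The seed fully determines every output.
#'
#' @param semi_axes_mm ellipsoid semi-axes (AP, ML, DV), mm.
#' @param center_mm ellipsoid centre (AP, ML, DV), mm; ML is distance from
#'   the midline.
#' @param spacing_um raster spacing, um.
#' @param ventricle_thickness_um thickness of the medial ventricle sheet, um.
#' @param subtypes subtypes to simulate (subset of SST/PV/TH).
#' @param baseline named per-subtype intensity at the region centre
#'   (female), cells/mm^3.
#' @param slopes per-subtype x (AP, ML, DV) matrix of female intensity
#'   slopes, cells/mm^3 per mm.
#' @param sex_baseline_offset named per-subtype male minus female intercept
#'   offset, cells/mm^3.
#' @param sex_slope_offset per-subtype x axis matrix of male minus female
#'   slope offsets.
#' @param hemisphere_sd SD of the Gaussian hemisphere random intercept,
#'   cells/mm^3.
#' @param section_noise_sd SD of the per-hemisphere, per-coronal-section
#'   Gaussian intensity noise, cells/mm^3.
#' @param section_pitch_um pitch of the noise sections along AP, um
#'   (the analysis plane pitch, so the plane-level residual SD is read off
#'   directly).
#' @param n_animals_per_sex animals per sex per subtype.
#' @param hemispheres_per_animal hemispheres contributed per animal.
#' @param seed RNG seed.
#' @return classed list \code{synthetic_config}.
#' @export
synthetic_config <- function(semi_axes_mm = c(2.0, 1.6, 1.7),
                             center_mm = c(0, 1.8, 0),
                             spacing_um = 50,
                             ventricle_thickness_um = 100,
                             subtypes = c("SST", "PV", "TH"),
                             baseline = c(SST = 1000, PV = 1200, TH = 1105),
                             slopes = rbind(SST = c(4.9, -32.4, 253.9),
                                            PV = c(-146.2, -61.34, -350.7),
                                            TH = c(212.9, -47.5, 441.6)),
                             sex_baseline_offset = c(SST = 0, PV = 0, TH = 190),
                             sex_slope_offset = rbind(SST = c(0, 0, 0),
                                                      PV = c(0, 124.3, 0),
                                                      TH = c(57.85, 0, 169.2)),
                             hemisphere_sd = 300,
                             section_noise_sd = 400,
                             section_pitch_um = 150,
                             n_animals_per_sex = 3L,
                             hemispheres_per_animal = 2L,
                             seed = 1L) {
  if (any(semi_axes_mm <= 0) || spacing_um <= 0 || section_pitch_um <= 0 ||
      ventricle_thickness_um <= 0)
    stopf("dimensions must be positive")
  if (hemisphere_sd < 0 || section_noise_sd < 0)
    stopf("noise SDs must be non-negative")
  subtypes <- match.arg(subtypes, CELL_SUBTYPES, several.ok = TRUE)
  colnames(slopes) <- colnames(sex_slope_offset) <- c("AP", "ML", "DV")
  cfg <- list(semi_axes_mm = semi_axes_mm, center_mm = center_mm,
              spacing_um = spacing_um,
              ventricle_thickness_um = ventricle_thickness_um,
              subtypes = subtypes,
              baseline = baseline[subtypes],
              slopes = slopes[subtypes, , drop = FALSE],
              sex_baseline_offset = sex_baseline_offset[subtypes],
              sex_slope_offset = sex_slope_offset[subtypes, , drop = FALSE],
              hemisphere_sd = hemisphere_sd,
              section_noise_sd = section_noise_sd,
              section_pitch_um = section_pitch_um,
              n_animals_per_sex = as.integer(n_animals_per_sex),
              hemispheres_per_animal = as.integer(hemispheres_per_animal),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build the toy reference space
#'
#' Deterministically rasterises the ellipsoidal region, the medial ventricle
#' sheet (a thin slab touching the region's medial face over a restricted
#' AP/DV patch, as the lateral ventricle abuts only part of the real
#' caudoputamen), and four octant-like parcels covering the region: TCP the
#' posterior cap, and the rest split into DMCP (dorsal medial), LCP
#' (lateral) and aVMCP (ventral medial).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return list: \code{region}, \code{ventricle} (\code{label_volume}s),
#'   \code{parcellation}, \code{frame}.
#' @export
make_toy_atlas <- function(cfg) {
  sp <- cfg$spacing_um / 1000
  a <- cfg$semi_axes_mm; ctr <- cfg$center_mm
  vt <- cfg$ventricle_thickness_um / 1000
  ml_medial <- ctr[2] - a[2]
  lo <- c(ctr[1] - a[1], min(ctr[2] - a[2], ml_medial - vt), ctr[3] - a[3]) -
    2 * sp
  hi <- c(ctr[1] + a[1], ctr[2] + a[2], ctr[3] + a[3]) + 2 * sp
  n <- as.integer(ceiling((hi - lo) / sp))
  frame <- coordinate_frame(origin_mm = lo + sp / 2,
                            axis_signs = c(1L, 1L, 1L), midline_ml_mm = 0)
  ap <- lo[1] + sp / 2 + (seq_len(n[1]) - 1) * sp
  ml <- lo[2] + sp / 2 + (seq_len(n[2]) - 1) * sp
  dv <- lo[3] + sp / 2 + (seq_len(n[3]) - 1) * sp

  e1 <- ((ap - ctr[1]) / a[1])^2
  e2 <- ((ml - ctr[2]) / a[2])^2
  e3 <- ((dv - ctr[3]) / a[3])^2
  inside <- outer(outer(e1, e2, "+"), e3, "+") <= 1
  region <- array(0L, dim = n)
  region[inside] <- 1L

  vent <- array(0L, dim = n)
  vml <- ml >= ml_medial - vt & ml < ml_medial
  vap <- ap >= ctr[1] - 1 & ap <= ctr[1] + 1
  vdv <- dv >= ctr[3] - 1 & dv <= ctr[3]
  vent[vap, vml, vdv] <- 1L

  parc <- array(0L, dim = n)
  post <- ap < ctr[1] - 0.5 * a[1]                # posterior cap -> TCP
  lat <- ml >= ctr[2]                             # lateral half -> LCP
  dors <- dv < ctr[3]                             # DV increases ventrally
  AP3 <- array(rep(post, times = n[2] * n[3]), dim = n)
  ML3 <- array(rep(rep(lat, each = n[1]), times = n[3]), dim = n)
  DV3 <- array(rep(dors, each = n[1] * n[2]), dim = n)
  parc[inside & AP3] <- 3L                                  # TCP
  parc[inside & !AP3 & ML3] <- 2L                           # LCP
  parc[inside & !AP3 & !ML3 & DV3] <- 1L                    # DMCP
  parc[inside & !AP3 & !ML3 & !DV3] <- 4L                   # aVMCP
  if (any((parc != 0L) != inside))
    stopf("internal error: parcels do not partition the region")

  region_vol <- label_volume(region, cfg$spacing_um, frame,
                             label_map = c(region = 1L))
  vent_vol <- label_volume(vent, cfg$spacing_um, frame,
                           label_map = c(ventricle = 1L))
  parc_vol <- label_volume(parc, cfg$spacing_um, frame,
                           label_map = c(DMCP = 1L, LCP = 2L, TCP = 3L,
                                         aVMCP = 4L))
  list(region = region_vol, ventricle = vent_vol,
       parcellation = parcellation(parc_vol, region_vol, region_labels = 1L),
       frame = frame)
}

#' Simulate cell point patterns from the inhomogeneous Poisson model
#'
#' For each hemisphere h (sex s) and subtype, the per-raster-voxel expected
#' count is \code{max(0, baseline + sex offset + u_h + sum_axis slope x
#' coordinate + eps_section) x voxel volume}, counts are drawn Poisson, and
#' cells are placed uniformly within their voxel. Left-side hemispheres are
#' generated with the ML coordinate reflected to the left of the midline, so
#' the mirroring stage of the pipeline is exercised.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param atlas result of \code{\link{make_toy_atlas}(cfg)}.
#' @return a \code{\link{cell_table}} (possibly empty, with a warning).
#' @export
simulate_cells <- function(cfg, atlas) {
  set.seed(cfg$seed)
  region <- atlas$region
  sp <- cfg$spacing_um / 1000
  vv <- sp^3
  idx <- which(region$labels == 1L, arr.ind = TRUE) - 1L
  centers <- index_to_mm(region, idx)
  # section index at the analysis-plane pitch, anchored like the voxel grid
  pitch <- cfg$section_pitch_um / 1000
  ap0 <- min(centers[, 1]) - sp / 2
  sec <- floor((centers[, 1] - ap0) / pitch) + 1L
  n_sec <- max(sec)
  lin <- cfg$slopes
  lin_off <- cfg$sex_slope_offset

  rows <- list()
  for (st in cfg$subtypes) {
    sexes <- rep(c("F", "M"), each = cfg$n_animals_per_sex)
    for (ai in seq_along(sexes)) {
      sex <- sexes[ai]
      animal <- sprintf("%s_%s%d", st, sex,
                        ((ai - 1L) %% cfg$n_animals_per_sex) + 1L)
      sides <- c("left", "right")[seq_len(cfg$hemispheres_per_animal)]
      for (side in sides) {
        u <- stats::rnorm(1, 0, cfg$hemisphere_sd)
        eps <- stats::rnorm(n_sec, 0, cfg$section_noise_sd)
        slope <- lin[st, ] + (sex == "M") * lin_off[st, ]
        base <- cfg$baseline[[st]] + (sex == "M") * cfg$sex_baseline_offset[[st]]
        lam <- base + u + eps[sec] +
          drop(sweep(centers, 2, cfg$center_mm, "-") %*% slope)
        lam <- pmax(0, lam)
        cnt <- stats::rpois(length(lam), lam * vv)
        tot <- sum(cnt)
        if (tot == 0L) next
        ridx <- rep.int(seq_along(cnt), cnt)
        pos <- centers[ridx, , drop = FALSE] +
          matrix(stats::runif(3 * tot, -sp / 2, sp / 2), ncol = 3)
        if (side == "left")
          pos[, 2] <- 2 * atlas$frame$midline_ml_mm - pos[, 2]
        rows[[length(rows) + 1L]] <- data.frame(
          ap_mm = pos[, 1], ml_mm = pos[, 2], dv_mm = pos[, 3],
          subtype = st, animal_id = animal,
          hemisphere_id = paste0(animal, "_", substr(side, 1, 1)),
          side = side, sex = sex, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    warnf("all intensities zero: empty cell table")
    empty <- data.frame(ap_mm = numeric(0), ml_mm = numeric(0),
                        dv_mm = numeric(0), subtype = character(0),
                        animal_id = character(0), hemisphere_id = character(0),
                        side = character(0), sex = character(0))
    class(empty) <- c("cell_table", "data.frame")
    return(empty)
  }
  cell_table(do.call(rbind, rows))
}

#' Slope-recovery experiment through the full pipeline
#'
#' Per replicate: simulate cells, mirror left hemispheres, filter to the
#' region, bin on the exclusion-applied 150 um grid, collapse along the
#' chosen axis, and fit the random-intercept gradient model. Reports bias,
#' RMSE, Wald 95% CI coverage of the generating slope, and the rejection
#' rate at \code{alpha} (the type-I error when the generating slope is
#' zero). The atlas and grid are fixed across replicates; replicate r uses
#' seed \code{cfg$seed + r}.
#'
#' @param cfg a single-subtype \code{\link{synthetic_config}}.
#' @param n_replicates number of simulated datasets.
#' @param axis profile axis.
#' @param edge_um analysis voxel edge.
#' @param alpha test level for the rejection rate.
#' @return list of class \code{recovery_report}: \code{true_slope},
#'   \code{replicates} (per-replicate estimate/se/p/covered), and summary
#'   fields \code{mean_estimate}, \code{bias}, \code{bias_pct}, \code{rmse},
#'   \code{coverage}, \code{rejection_rate}.
#' @export
recovery_experiment <- function(cfg, n_replicates = 100L,
                                axis = c("AP", "ML", "DV"), edge_um = 150,
                                alpha = 0.05) {
  axis <- match.arg(axis)
  if (length(cfg$subtypes) != 1L)
    stopf("recovery_experiment expects a single-subtype config")
  st <- cfg$subtypes
  atlas <- make_toy_atlas(cfg)
  grid <- build_voxel_grid(atlas$region, 1L, edge_um = edge_um)
  grid <- chebyshev_exclude(grid, atlas$region, atlas$ventricle)
  ax <- axis_index(axis)
  # pooled (sex-balanced) generating slope seen by the sex-free model
  true_slope <- cfg$slopes[st, ax] + 0.5 * cfg$sex_slope_offset[st, ax]

  reps <- data.frame(estimate = numeric(n_replicates),
                     se = numeric(n_replicates), p = numeric(n_replicates))
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    cells <- simulate_cells(cfg_r, atlas)
    cells <- mirror_left_to_right(cells, atlas$frame)
    cells <- filter_to_region(cells, atlas$region, 1L, quiet = TRUE)
    prof <- collapse_axis(split_hemispheres(cells), grid, axis, n_boot = 0L)
    fit <- fit_axis_gradient(prof)
    reps$estimate[r] <- fit$coefficients[["coordinate"]]
    reps$se[r] <- fit$se[["coordinate"]]
    reps$p[r] <- fit$p[["coordinate"]]
  }
  zq <- stats::qnorm(1 - alpha / 2)
  reps$covered <- abs(reps$estimate - true_slope) <= zq * reps$se
  out <- list(true_slope = unname(true_slope), axis = axis, subtype = st,
              replicates = reps,
              mean_estimate = mean(reps$estimate),
              bias = mean(reps$estimate) - unname(true_slope),
              bias_pct = if (true_slope != 0)
                100 * (mean(reps$estimate) - true_slope) / true_slope
                else NA_real_,
              rmse = sqrt(mean((reps$estimate - true_slope)^2)),
              coverage = mean(reps$covered),
              rejection_rate = mean(reps$p < alpha),
              n_replicates = as.integer(n_replicates))
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s %s axis, %d replicates\n", x$subtype,
              x$axis, x$n_replicates))
  cat(sprintf("  true slope %.2f; mean estimate %.2f (bias %.2f%s); rmse %.2f\n",
              x$true_slope, x$mean_estimate, x$bias,
              if (!is.na(x$bias_pct)) sprintf(" = %.2f%%", x$bias_pct) else "",
              x$rmse))
  cat(sprintf("  95%% CI coverage %.3f; rejection rate %.3f\n",
              x$coverage, x$rejection_rate))
  invisible(x)
}
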