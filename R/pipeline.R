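#' Default run configuration
#'
#' All analysis constants of the published pipeline in one audited place:
#' 150 um voxels, 50 um boundary and 175 um ventricle Chebyshev exclusions,
#' 1000 hemisphere bootstraps, Gaussian sigma 0.5 voxel, 15 pooled quantile
#' thresholds, plane-level mixed-model observations, ML estimation. YAML
#' config values override these defaults (\code{\link{read_run_config}}).
#'
#' @return nested list of class \code{run_config}.
#' @export
default_run_config <- function() {
  structure(list(
    paths = list(cells = NULL,       # named list subtype -> CSV path
                 region = NULL, ventricle = NULL, parcellation = NULL,
                 out = "striatlas_out"),
    simulate = TRUE,                 # no paths: use the synthetic generator
    synthetic = list(),              # overrides for synthetic_config()
    frame = list(origin_mm = c(5.40, -5.70, 0), axis_signs = c(-1, 1, 1),
                 midline_ml_mm = 0),
    columns = NULL, units = "mm",
    grid = list(edge_um = 150, d_boundary_um = 50, d_ventricle_um = 175),
    density = list(n_boot = 1000, sigma_voxel = 0.5, n_bins = 15,
                   bootstrap_unit = "hemisphere"),
    models = list(lme_unit = "plane", method = "ML", sex = TRUE),
    seed = 1L), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Values present in the file override \code{\link{default_run_config}};
#' everything else keeps the published defaults.
#'
#' @param path YAML file path (\code{NULL} for pure defaults).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
    class(cfg) <- "run_config"
  }
  known <- c("paths", "simulate", "synthetic", "frame", "columns", "units",
             "grid", "density", "models", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L)
    stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  cfg
}

#' Assemble pipeline inputs (atlas volumes, mirrored region-filtered cells,
#' exclusion-applied grid)
#'
#' With \code{simulate = TRUE} the toy atlas and synthetic cells are
#' generated from \code{config$synthetic}; otherwise label volumes and cell
#' CSVs are loaded from \code{config$paths}. In both cases left-hemisphere
#' cells are mirrored across the midline, cells are filtered to the region,
#' and the analysis grid is built and Chebyshev-eroded.
#'
#' @param config a \code{run_config}.
#' @return list: \code{region}, \code{ventricle}, \code{parcellation},
#'   \code{frame}, \code{grid}, \code{cells_by_subtype} (list of named
#'   per-hemisphere cell-table lists), \code{config}.
#' @export
pipeline_inputs <- function(config = default_run_config()) {
  if (isTRUE(config$simulate)) {
    sargs <- config$synthetic
    sargs$seed <- sargs$seed %||% config$seed
    scfg <- do.call(synthetic_config, sargs)
    atlas <- make_toy_atlas(scfg)
    cells <- simulate_cells(scfg, atlas)
    region <- atlas$region; ventricle <- atlas$ventricle
    parc <- atlas$parcellation; frame <- atlas$frame
    region_labels <- 1L
  } else {
    frame <- do.call(coordinate_frame, config$frame)
    if (is.null(config$paths$region)) stopf("paths$region is required")
    region <- load_label_volume(config$paths$region, frame = frame)
    region_labels <- region$label_map
    ventricle <- if (!is.null(config$paths$ventricle))
      load_label_volume(config$paths$ventricle, frame = frame) else NULL
    parc <- if (!is.null(config$paths$parcellation)) {
      pv <- load_label_volume(config$paths$parcellation, frame = frame,
                              label_map = stats::setNames(1:4, SUBREGION_NAMES))
      parcellation(pv, region, region_labels)
    } else NULL
    if (is.null(config$paths$cells)) stopf("paths$cells is required")
    cells <- do.call(rbind, lapply(names(config$paths$cells), function(st) {
      d <- read_cells(config$paths$cells[[st]], columns = config$columns,
                      units = config$units)
      if (!all(d$subtype == st))
        stopf("cells file for %s contains other subtypes", st)
      d
    }))
    cells <- cell_table(cells)
  }
  cells <- mirror_left_to_right(cells, frame)
  cells <- filter_to_region(cells, region, region_labels, quiet = TRUE)
  grid <- build_voxel_grid(region, region_labels,
                           edge_um = config$grid$edge_um)
  grid <- chebyshev_exclude(grid, region, ventricle,
                            d_boundary_um = config$grid$d_boundary_um,
                            d_ventricle_um = config$grid$d_ventricle_um)
  by_subtype <- lapply(split(as.data.frame(cells), cells$subtype),
                       function(d) {
                         class(d) <- c("cell_table", "data.frame")
                         split_hemispheres(d)
                       })
  list(region = region, ventricle = ventricle, parcellation = parc,
       frame = frame, grid = grid, cells_by_subtype = by_subtype,
       config = config)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the atlas stage: bootstrap density maps, smoothing, pooled quantile
#' bins and the predominance map
#'
#' Writes, under \code{out_dir}: per-subtype NRRD volumes (bootstrap mean,
#' SE, quantile bin index), a long-format CSV of per-voxel values, the
#' predominance NRRD with its JSON code table, and a provenance record.
#' Identical config + seed reproduce bit-identical outputs.
#'
#' @param config a \code{run_config} (or YAML path).
#' @param out_dir output directory (default \code{config$paths$out}).
#' @param inputs optional precomputed \code{\link{pipeline_inputs}}.
#' @return invisibly, list of \code{maps}, \code{bins}, \code{predominance}.
#' @export
run_atlas <- function(config = default_run_config(), out_dir = NULL,
                      inputs = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(inputs)) inputs <- pipeline_inputs(config)
  out_dir <- out_dir %||% config$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- inputs$grid
  dn <- config$density
  maps <- list()
  for (i in seq_along(inputs$cells_by_subtype)) {
    st <- names(inputs$cells_by_subtype)[i]
    m <- bootstrap_density(inputs$cells_by_subtype[[st]], grid,
                           n_boot = dn$n_boot, seed = config$seed + i,
                           unit = dn$bootstrap_unit)
    maps[[st]] <- smooth_density(m, sigma_voxel = dn$sigma_voxel)
  }
  bins <- pooled_quantile_bins(maps, n_bins = dn$n_bins)
  pred <- if (length(maps) >= 2L) predominance(maps) else NULL

  incl <- which(grid$included)
  ctr <- voxel_centers(grid)
  long <- do.call(rbind, lapply(names(maps), function(st) {
    data.frame(voxel = incl, ap_mm = ctr[, 1], ml_mm = ctr[, 2],
               dv_mm = ctr[, 3], subtype = st,
               mean_density = maps[[st]]$mean_density[incl],
               se_density = maps[[st]]$se_density[incl],
               bin = bins$bin_index[[st]][incl])
  }))
  utils::write.csv(long, file.path(out_dir, "voxel_densities.csv"),
                   row.names = FALSE, quote = FALSE)
  for (st in names(maps)) {
    arr <- maps[[st]]$mean_density; arr[is.na(arr)] <- -1
    write_nrrd(arr, file.path(out_dir, sprintf("density_mean_%s.nrrd", st)),
               spacing_mm = grid$edge_um / 1000)
    arr <- maps[[st]]$se_density; arr[is.na(arr)] <- -1
    write_nrrd(arr, file.path(out_dir, sprintf("density_se_%s.nrrd", st)),
               spacing_mm = grid$edge_um / 1000)
    arr <- bins$bin_index[[st]]; arr[is.na(arr)] <- 0L
    write_nrrd(arr, file.path(out_dir, sprintf("density_bin_%s.nrrd", st)),
               spacing_mm = grid$edge_um / 1000)
  }
  if (!is.null(pred)) {
    arr <- pred$labels; arr[is.na(arr)] <- 0L
    write_nrrd(arr, file.path(out_dir, "predominance.nrrd"),
               spacing_mm = grid$edge_um / 1000)
    write_json_out(list(codes = stats::setNames(as.list(seq_along(pred$subtypes)),
                                                pred$subtypes),
                        n_ties = pred$n_ties),
                   file.path(out_dir, "predominance_codes.json"))
  }
  write_json_out(list(stage = "atlas", seed = config$seed,
                      n_included_voxels = length(incl),
                      included_volume_mm3 = length(incl) * grid$voxel_volume_mm3,
                      config = config[c("grid", "density", "seed")]),
                 file.path(out_dir, "provenance_atlas.json"))
  invisible(list(maps = maps, bins = bins, predominance = pred,
                 inputs = inputs))
}

#' Run the gradients stage: axis profiles and mixed-model fits
#'
#' For every subtype and axis (AP, ML, DV), collapses densities into 150 um
#' planes, fits Density ~ Coordinate + (1 | Hemisphere), and (when both
#' sexes are present and \code{models$sex} is on) the sex-interaction model.
#' Writes tidy profile CSVs and JSON/CSV fit tables.
#'
#' @inheritParams run_atlas
#' @return invisibly, list of \code{profiles}, \code{fits} (data.frame),
#'   \code{sex_fits}.
#' @export
run_gradients <- function(config = default_run_config(), out_dir = NULL,
                          inputs = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(inputs)) inputs <- pipeline_inputs(config)
  out_dir <- out_dir %||% config$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- inputs$grid
  axes <- c("AP", "ML", "DV")
  profiles <- list(); fit_rows <- list(); sex_fits <- list(); long_all <- list()
  for (st in names(inputs$cells_by_subtype)) {
    hems <- inputs$cells_by_subtype[[st]]
    for (ax in axes) {
      key <- paste(st, ax, sep = "_")
      prof <- collapse_axis(hems, grid, ax, n_boot = config$density$n_boot,
                            seed = config$seed + axis_index(ax))
      profiles[[key]] <- prof
      long_all[[key]] <- cbind(subtype = st, profile_long(prof))
      if (config$models$lme_unit == "voxel") {
        obs <- axis_observations(hems, grid, ax, unit = "voxel")
        X <- cbind("(Intercept)" = 1, coordinate = obs$plane_center_mm)
        fit <- fit_random_intercept(obs$density, X, obs$hemisphere_id,
                                    method = config$models$method)
      } else {
        fit <- fit_axis_gradient(prof, method = config$models$method)
      }
      row <- data.frame(subtype = st, axis = ax,
                        beta = fit$coefficients[["coordinate"]],
                        se = fit$se[["coordinate"]],
                        z = fit$z[["coordinate"]], p = fit$p[["coordinate"]],
                        sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
                        n_obs = fit$n_obs, n_groups = fit$n_groups)
      if (isTRUE(config$models$sex) && length(unique(prof$sex)) == 2L) {
        sf <- fit_axis_sex_interaction(prof, method = config$models$method)
        sex_fits[[key]] <- sf
        row$beta_female <- sf$simple_slopes$estimate[1]
        row$beta_male <- sf$simple_slopes$estimate[2]
        row$beta_sex_interaction <- sf$interaction$estimate
        row$p_sex_interaction <- sf$interaction$p
      }
      fit_rows[[key]] <- row
    }
  }
  fits <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))
  utils::write.csv(do.call(rbind, c(long_all, list(make.row.names = FALSE))),
                   file.path(out_dir, "axis_profiles.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fits, file.path(out_dir, "gradient_fits.csv"),
                   row.names = FALSE, quote = FALSE)
  write_json_out(fits, file.path(out_dir, "gradient_fits.json"))
  invisible(list(profiles = profiles, fits = fits, sex_fits = sex_fits,
                 inputs = inputs))
}

#' Run the subregion stage: parcel densities and composition tests
#'
#' Builds the per-hemisphere subregion density table and runs both pivots of
#' the composition analysis — subtype differences within each subregion and
#' subregion differences within each subtype — with Sidak-corrected pairwise
#' contrasts. Writes the density table, omnibus and pairwise CSVs.
#'
#' @inheritParams run_atlas
#' @return invisibly, list of \code{table}, \code{within_subregion},
#'   \code{within_subtype}.
#' @export
run_subregions <- function(config = default_run_config(), out_dir = NULL,
                           inputs = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(inputs)) inputs <- pipeline_inputs(config)
  out_dir <- out_dir %||% config$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputs$parcellation)) stopf("no parcellation available")
  hems <- do.call(c, unname(inputs$cells_by_subtype))
  tab <- subregion_density_table(hems, inputs$parcellation)
  res <- list(table = tab)
  for (mode in c("within_subregion", "within_subtype")) {
    ct <- composition_tests(tab, mode = mode)
    res[[mode]] <- ct
    omni <- do.call(rbind, lapply(names(ct), function(s)
      cbind(data.frame(stratum = s), ct[[s]]$omnibus)))
    pw <- do.call(rbind, lapply(names(ct), function(s)
      cbind(data.frame(stratum = s), ct[[s]]$pairwise)))
    utils::write.csv(omni, file.path(out_dir, sprintf("%s_omnibus.csv", mode)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(pw, file.path(out_dir, sprintf("%s_pairwise.csv", mode)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(tab, file.path(out_dir, "subregion_densities.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(c(res, list(inputs = inputs)))
}
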