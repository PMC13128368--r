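box_grid <- function(nx = 8L, ny = 4L, nz = 4L) {
  fr <- coordinate_frame(origin_mm = c(0.075, 0.075, 0.075),
                         axis_signs = c(1, 1, 1))
  lab <- array(1L, dim = c(nx, ny, nz))
  build_voxel_grid(label_volume(lab, 150, fr), 1L, 150)
}

# deterministic cells: k cells at each included voxel centre
cells_per_voxel <- function(grid, k, hemisphere = "A_r", sex = "F",
                            subtype = "TH") {
  ctr <- voxel_centers(grid)
  ctr <- ctr[rep(seq_len(nrow(ctr)), each = k), , drop = FALSE]
  make_cells(ctr[, 1], ctr[, 2], ctr[, 3], subtype = subtype,
             hemisphere = hemisphere, sex = sex,
             animal = sub("_[lr]$", "", hemisphere))
}

test_that("axis collapse gives flat profiles for uniform cells and exact slab
           arithmetic", {
  grid <- box_grid()
  hems <- list(A_r = cells_per_voxel(grid, 3L))
  for (ax in c("AP", "ML", "DV")) {
    prof <- collapse_axis(hems, grid, ax, n_boot = 0)
    dens <- prof$density[1, ]
    expect_equal(dens, rep(3 / grid$voxel_volume_mm3, length(dens)),
                 info = ax)
  }
  # all cells in one slab: single nonzero plane, density = count / volume
  one <- make_cells(rep(0.2, 7), runif(7, 0.0, 0.6), runif(7, 0.0, 0.6),
                    hemisphere = "A_r")
  prof <- collapse_axis(list(A_r = one), grid, "AP", n_boot = 0)
  slab_vol <- 4 * 4 * grid$voxel_volume_mm3
  expect_equal(unname(prof$density[1, 2]), 7 / slab_vol)
  expect_equal(sum(prof$density[1, ] > 0), 1L)
  expect_error(collapse_axis(hems, grid, "XX"), "arg")
})

test_that("slab densities equal the brute-force per-slab count/volume on the
           eroded ellipsoid", {
  cfg <- tiny_config(seed = 31L)
  atlas <- make_toy_atlas(cfg)
  grid <- build_voxel_grid(atlas$region, 1L, 150)
  grid <- chebyshev_exclude(grid, atlas$region, atlas$ventricle)
  cells <- simulate_cells(cfg, atlas)
  cells <- mirror_left_to_right(cells, atlas$frame)
  cells <- filter_to_region(cells, atlas$region, 1L, quiet = TRUE)
  hems <- as_hemi_list(cells)
  prof <- collapse_axis(hems, grid, "DV", n_boot = 0)
  # oracle: per hemisphere, count cells whose voxel is included per DV plane
  for (h in seq_along(hems)) {
    cnt <- bf_voxel_counts(hems[[h]], grid)
    cnt[!grid$included] <- 0L
    plane_counts <- apply(cnt, 3, sum)
    vols <- apply(grid$included, 3, sum) * grid$voxel_volume_mm3
    keep <- vols > 0
    expect_equal(prof$density[names(hems)[h], ],
                 unname(plane_counts[keep] / vols[keep]))
  }
  # invariant to hemisphere and cell ordering
  perm <- rev(seq_along(hems))
  shuf <- lapply(hems[perm], function(d) d[sample(nrow(d)), , drop = FALSE])
  prof2 <- collapse_axis(shuf, grid, "DV", n_boot = 0)
  expect_equal(prof2$density[rownames(prof$density), ], prof$density)
})

test_that("noise-free linear gradients are recovered exactly (OLS limit)", {
  grid <- box_grid(nx = 10L)
  # counts rise by exactly 2 cells per 150 um plane in both hemispheres, so
  # the generating slope is 2 / (0.15 mm x slab volume) with zero noise
  planes <- grid$shape[1]
  slab_vol <- 16 * grid$voxel_volume_mm3
  true_slope <- 2 / (0.15 * slab_vol)
  hems <- lapply(c(A_r = "A_r", B_r = "B_r"), function(h) {
    rows <- lapply(seq_len(planes), function(i) {
      ap <- grid$origin_mm[1] + (i - 0.5) * 0.15
      k <- 50L + 2L * i
      ctr <- voxel_centers(grid)
      slab <- ctr[abs(ctr[, 1] - ap) < 1e-9, , drop = FALSE]
      idx <- rep(seq_len(nrow(slab)), length.out = k)
      make_cells(slab[idx, 1], slab[idx, 2], slab[idx, 3], hemisphere = h,
                 animal = sub("_r", "", h))
    })
    cell_table(do.call(rbind, lapply(rows, as.data.frame)))
  })
  prof <- collapse_axis(hems, grid, "AP", n_boot = 0)
  # zero-noise limit: lme4 emits degenerate-fit convergence warnings but the
  # fixed effects equal the OLS solution
  fit <- suppressWarnings(fit_axis_gradient(prof))
  expect_equal(fit$coefficients[["coordinate"]], true_slope,
               tolerance = 1e-6)
  expect_lt(fit$sigma_u2, 1e-6)
  expect_equal(fit$n_obs, 2L * planes)
})

test_that("a generated AP gradient at study scale is recovered within 2 SEs", {
  cfg <- recovery_config(slope_ap = 240, seed = 77L)
  atlas <- make_toy_atlas(cfg)
  grid <- build_voxel_grid(atlas$region, 1L, 150)
  grid <- chebyshev_exclude(grid, atlas$region, atlas$ventricle)
  cells <- simulate_cells(cfg, atlas)
  cells <- mirror_left_to_right(cells, atlas$frame)
  cells <- filter_to_region(cells, atlas$region, 1L, quiet = TRUE)
  hems <- as_hemi_list(cells)
  expect_equal(length(hems), 12L)
  prof <- collapse_axis(hems, grid, "AP", n_boot = 0)
  # 150 um planes over the ~4 mm AP extent, within the study's plane range
  expect_true(ncol(prof$density) >= 23L && ncol(prof$density) <= 27L)
  fit <- fit_axis_gradient(prof)
  expect_true(abs(fit$coefficients[["coordinate"]] - 240) <=
                2 * fit$se[["coordinate"]])
  expect_equal(fit$n_obs, 12L * ncol(prof$density))
  expect_equal(fit$n_groups, 12L)
})

test_that("sex-interaction model: null interaction, offset recovery, and the
           simple-slope identity", {
  # null: identical generating slopes for the sexes
  cfg0 <- recovery_config(slope_ap = 200, sex_slope_ap = 0, seed = 55L)
  atlas <- make_toy_atlas(cfg0)
  grid <- build_voxel_grid(atlas$region, 1L, 150)
  grid <- chebyshev_exclude(grid, atlas$region, atlas$ventricle)
  run_sex_fit <- function(cfg) {
    cells <- simulate_cells(cfg, atlas)
    cells <- mirror_left_to_right(cells, atlas$frame)
    cells <- filter_to_region(cells, atlas$region, 1L, quiet = TRUE)
    prof <- collapse_axis(as_hemi_list(cells), grid, "AP", n_boot = 0)
    fit_axis_sex_interaction(prof)
  }
  sf0 <- run_sex_fit(cfg0)
  expect_lt(abs(sf0$interaction$z), 3)
  # male slope = female slope + 60 in the generator
  sf1 <- run_sex_fit(recovery_config(slope_ap = 200, sex_slope_ap = 60,
                                     seed = 56L))
  expect_true(abs(sf1$interaction$estimate - 60) <= 2 * sf1$interaction$se)
  # algebraic identity: beta_male - beta_female = interaction, exactly
  expect_equal(sf1$simple_slopes$estimate[2] - sf1$simple_slopes$estimate[1],
               sf1$interaction$estimate, tolerance = 1e-10)
  expect_equal(sf1$simple_slopes$estimate[1],
               unname(sf1$fit$coefficients["coordinate"]))
  # single-sex input errors
  one_sex <- recovery_config(seed = 57L)
  cells <- simulate_cells(one_sex, atlas)
  cells <- cells[cells$sex == "F", ]
  class(cells) <- c("cell_table", "data.frame")
  cells <- mirror_left_to_right(cells, atlas$frame)
  prof <- collapse_axis(as_hemi_list(cells), grid, "AP", n_boot = 0)
  expect_error(fit_axis_sex_interaction(prof), "both sexes")
})
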