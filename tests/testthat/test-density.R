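one_voxel_grid <- function() {
  fr <- coordinate_frame(origin_mm = c(0.025, 0.025, 0.025),
                         axis_signs = c(1, 1, 1))
  lab <- array(1L, dim = c(6L, 6L, 6L))
  vol <- label_volume(lab, 50, fr)
  build_voxel_grid(vol, 1L, 150)   # 2 x 2 x 2 grid, all included
}

test_that("voxel counting obeys the half-open rule and conserves cells", {
  grid <- one_voxel_grid()
  cells <- make_cells(c(0.05, 0.10, 0.14), c(0.05, 0.05, 0.05),
                      c(0.05, 0.05, 0.05))
  cnt <- voxel_counts(cells, grid)
  expect_equal(cnt[1, 1, 1], 3L)
  expect_equal(sum(cnt), 3L)
  # density of 3 cells in one 150 um voxel
  expect_equal(cnt[1, 1, 1] / grid$voxel_volume_mm3, 888.888889,
               tolerance = 1e-6)
  # cell exactly on the shared face at 0.15 goes to the higher-index voxel
  face <- make_cells(0.15, 0.05, 0.05)
  cf <- voxel_counts(face, grid)
  expect_equal(cf[2, 1, 1], 1L)
  expect_equal(cf[1, 1, 1], 0L)
  expect_equal(sum(cf), 1L)
})

test_that("voxel counts match the per-point brute-force assignment", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  grid <- build_voxel_grid(atlas$region, 1L, 150)
  set.seed(3)
  n <- 2000
  cells <- make_cells(runif(n, -0.8, 0.8), runif(n, 0.0, 1.4),
                      runif(n, -0.8, 0.8))
  cnt <- voxel_counts(cells, grid)
  expect_identical(unclass(cnt)[seq_along(cnt)],
                   as.vector(bf_voxel_counts(cells, grid)))
  # conservation: binned inside + outside-grid + outside-included = total
  expect_equal(attr(cnt, "n_included") + attr(cnt, "n_outside_included") +
                 attr(cnt, "n_outside_grid"), n)
})

test_that("bootstrap density is seed-deterministic with exact degenerate SEs", {
  grid <- one_voxel_grid()
  h1 <- make_cells(runif(20, 0, 0.29), runif(20, 0, 0.29), runif(20, 0, 0.29),
                   hemisphere = "A_r")
  # one hemisphere: every replicate identical, se = 0
  m1 <- bootstrap_density(list(A_r = h1), grid, n_boot = 50, seed = 1)
  expect_true(all(m1$se_density[grid$included] == 0))
  expect_equal(m1$mean_density[grid$included],
               voxel_counts(h1, grid)[grid$included] / (1 * grid$voxel_volume_mm3))
  # two identical hemispheres: still se = 0
  h2 <- h1; h2$hemisphere_id <- "B_r"; h2$animal_id <- "B"
  m2 <- bootstrap_density(list(A_r = h1, B_r = h2), grid, n_boot = 50, seed = 1)
  expect_true(all(m2$se_density[grid$included] == 0))
  # determinism under a fixed seed
  hs <- lapply(1:4, function(i) {
    d <- make_cells(runif(30, 0, 0.29), runif(30, 0, 0.29), runif(30, 0, 0.29),
                    hemisphere = paste0("H", i, "_r"), animal = paste0("H", i))
    d
  })
  names(hs) <- paste0("H", 1:4, "_r")
  a <- bootstrap_density(hs, grid, n_boot = 100, seed = 9)
  b <- bootstrap_density(hs, grid, n_boot = 100, seed = 9)
  expect_identical(a$mean_density, b$mean_density)
  expect_identical(a$se_density, b$se_density)
  expect_error(bootstrap_density(hs, grid, n_boot = 0), "n_boot")
})

test_that("bootstrap mean approaches the plain across-hemisphere mean", {
  # E[mean of a with-replacement resample] = plain mean; check within 3
  # Monte-Carlo SEs at n_boot = 200
  grid <- one_voxel_grid()
  set.seed(21)
  hs <- lapply(1:4, function(i) {
    make_cells(runif(10 * i, 0, 0.29), runif(10 * i, 0, 0.29),
               runif(10 * i, 0, 0.29),
               hemisphere = paste0("H", i, "_r"), animal = paste0("H", i))
  })
  names(hs) <- paste0("H", 1:4, "_r")
  m <- bootstrap_density(hs, grid, n_boot = 200, seed = 33)
  vol <- grid$voxel_volume_mm3
  dens <- sapply(hs, function(h) voxel_counts(h, grid)[grid$included] / vol)
  expected <- rowMeans(dens)
  mc_se <- m$se_density[grid$included] / sqrt(200)
  got <- m$mean_density[grid$included]
  expect_true(all(abs(got - expected) <= 3 * pmax(mc_se, 1e-9)))
})

test_that("masked Gaussian smoothing: identity, constants, and the brute-force
           convolution", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  grid <- build_voxel_grid(atlas$region, 1L, 150)
  vals <- array(NA_real_, grid$shape)
  set.seed(5)
  vals[grid$included] <- runif(sum(grid$included), 0, 100)
  map <- structure(list(subtype = "SST", grid = grid, mean_density = vals,
                        se_density = vals * 0, n_hemispheres = 1L,
                        n_boot = 1L), class = "density_map")
  expect_identical(smooth_density(map, 0)$mean_density, vals)
  expect_error(smooth_density(map, -1), "non-negative")
  # constants preserved under renormalized kernel
  cmap <- map; cmap$mean_density[grid$included] <- 7.5
  sm <- smooth_density(cmap, 0.5)
  expect_equal(sm$mean_density[grid$included],
               rep(7.5, sum(grid$included)))
  # irregular mask vs direct triple-sum oracle
  sm2 <- smooth_density(map, 0.5)
  oracle <- bf_smooth(ifelse(is.na(vals), 0, vals), grid$included, 0.5)
  expect_equal(sm2$mean_density, oracle)
  expect_true(all(sm2$mean_density[grid$included] >= 0))
  # single nonzero voxel on a fully-included 7^3 grid = plain convolution
  fr <- coordinate_frame(origin_mm = c(0.025, 0.025, 0.025),
                         axis_signs = c(1, 1, 1))
  lab <- array(1L, dim = c(21L, 21L, 21L))
  full <- build_voxel_grid(label_volume(lab, 50, fr), 1L, 150)
  v2 <- array(0, full$shape); v2[4, 4, 4] <- 100
  m2 <- structure(list(subtype = "SST", grid = full, mean_density = v2,
                       se_density = v2 * 0, n_hemispheres = 1L, n_boot = 1L),
                  class = "density_map")
  got <- smooth_density(m2, 0.5)$mean_density
  expect_equal(got, bf_smooth(v2, full$included, 0.5))
})

fake_map <- function(grid, values, subtype = "SST") {
  arr <- array(NA_real_, grid$shape)
  arr[grid$included] <- values
  structure(list(subtype = subtype, grid = grid, mean_density = arr,
                 se_density = arr * 0, n_hemispheres = 1L, n_boot = 1L),
            class = "density_map")
}

test_that("pooled quantile bins slice the pooled distribution as sorted", {
  fr <- coordinate_frame(origin_mm = c(0.075, 0.075, 0.075),
                         axis_signs = c(1, 1, 1))
  lab <- array(1L, dim = c(10L, 15L, 1L))   # 150 included voxels
  grid <- build_voxel_grid(label_volume(lab, 150, fr), 1L, 150)
  expect_equal(sum(grid$included), 150L)
  set.seed(8)
  vals <- sample(1:150)
  qb <- pooled_quantile_bins(list(fake_map(grid, vals)), n_bins = 15)
  bins <- qb$bin_index[[1]][grid$included]
  # sort-and-slice oracle: 10 values per bin, in sorted order
  expect_equal(as.vector(table(bins)), rep(10L, 15))
  expect_equal(bins[order(vals)], rep(1:15, each = 10))
  expect_false(is.unsorted(qb$thresholds))
  # the map's maximum voxel is always in the top bin
  expect_equal(bins[which.max(vals)], 15L)
  # degenerate all-equal densities: thresholds tie, everything in bin 15
  qb2 <- pooled_quantile_bins(list(fake_map(grid, rep(4, 150))), n_bins = 15)
  expect_true(all(qb2$thresholds == 4))
  expect_true(all(qb2$bin_index[[1]][grid$included] == 15L))
  expect_error(pooled_quantile_bins(list(fake_map(grid, vals)), n_bins = 1),
               "n_bins")
})

test_that("predominance takes the per-voxel argmax with SST-first ties", {
  grid <- one_voxel_grid()
  n <- sum(grid$included)
  set.seed(12)
  maps <- list(SST = fake_map(grid, runif(n), "SST"),
               PV = fake_map(grid, runif(n), "PV"),
               TH = fake_map(grid, runif(n), "TH"))
  pm <- predominance(maps)
  dm <- cbind(maps$SST$mean_density[grid$included],
              maps$PV$mean_density[grid$included],
              maps$TH$mean_density[grid$included])
  expect_equal(pm$labels[grid$included],
               apply(dm, 1, which.max))
  # forced argmax and an exact three-way tie
  m2 <- list(SST = fake_map(grid, rep(5, n), "SST"),
             PV = fake_map(grid, rep(9, n), "PV"),
             TH = fake_map(grid, rep(1, n), "TH"))
  expect_true(all(predominance(m2)$labels[grid$included] == 2L))
  m3 <- list(SST = fake_map(grid, rep(2, n), "SST"),
             PV = fake_map(grid, rep(2, n), "PV"),
             TH = fake_map(grid, rep(2, n), "TH"))
  pm3 <- predominance(m3)
  expect_true(all(pm3$labels[grid$included] == 1L))  # SST by priority
  expect_equal(pm3$n_ties, n)
  expect_error(predominance(m2[1]), "at least two")
})
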