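test_that("sidak_adjust matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(1, 4), 1)
  expect_equal(sidak_adjust(0.2, 1), 0.2)       # m = 1 identity
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 5)) >= 0))          # monotone in p
  expect_true(all(sidak_adjust(p, 3) <= sidak_adjust(p, 6)))  # monotone in m
  expect_true(all(sidak_adjust(p, 4) >= p))                # adjusted >= raw
  expect_error(sidak_adjust(1.2, 3), "\\[0, 1\\]")
  expect_error(sidak_adjust(0.5, 0), "positive integer")
})

test_that("subregion assignment matches per-point lookup on the toy parcels", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  parc <- atlas$parcellation
  set.seed(19)
  n <- 1000
  cells <- make_cells(runif(n, -0.7, 0.7), runif(n, 0.1, 1.3),
                      runif(n, -0.7, 0.7))
  got <- assign_subregion(cells, parc)
  expect_equal(got$subregion, bf_assign(cells, parc))
  expect_true(any(got$subregion == "unassigned"))
  expect_true(all(SUBREGION_NAMES_used <- setdiff(unique(got$subregion),
                                                  "unassigned") %in%
                    c("DMCP", "LCP", "TCP", "aVMCP")))
  # partition: assigned + unassigned = all cells
  expect_equal(sum(table(got$subregion)), n)
  # a cell placed dead-centre of the dorsal-medial anterior octant -> DMCP
  dm <- make_cells(0, 0.45, -0.25)
  expect_equal(assign_subregion(dm, parc)$subregion, "DMCP")
  out <- make_cells(5, 5, 5)
  expect_equal(assign_subregion(out, parc)$subregion, "unassigned")
})

test_that("subregion densities are count/volume with empty parcels at zero", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  parc <- atlas$parcellation
  # 10 deterministic cells into DMCP only
  dm <- make_cells(rep(0, 10), rep(0.45, 10), rep(-0.25, 10))
  tab <- subregion_density_table(list(A_r = dm), parc)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$density[tab$subregion == "DMCP"],
               10 / parc$volumes_mm3[["DMCP"]])
  expect_equal(tab$density[tab$subregion == "TCP"], 0)
  # generator with uniform intensity: densities within 3 Poisson SEs
  cfg2 <- tiny_config(seed = 23L)
  cells <- simulate_cells(cfg2, make_toy_atlas(cfg2))
  cells <- mirror_left_to_right(cells, atlas$frame)
  tab2 <- subregion_density_table(as_hemi_list(cells), parc)
  lam <- 2000
  for (r in seq_len(nrow(tab2))) {
    v <- parc$volumes_mm3[[tab2$subregion[r]]]
    se <- sqrt(lam / v)
    expect_lt(abs(tab2$density[r] - lam), 4 * se)
  }
  # zero-volume parcel errors
  bad <- parc; bad$volumes_mm3[["TCP"]] <- 0
  expect_error(subregion_density_table(list(A_r = dm), bad), "zero-volume")
})

test_that("composition tests: exact null, power under forced differences,
           and the two-pivot consistency", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  parc <- atlas$parcellation
  # build a density table directly: 6 hemispheres x 3 subtypes x 4 parcels
  set.seed(77)
  mk_tab <- function(mu_fun) {
    rows <- list()
    for (st in c("SST", "PV", "TH")) for (h in 1:6) {
      hid <- sprintf("%s_h%d", st, h)
      u <- rnorm(1, 0, 20)
      for (sr in c("DMCP", "LCP", "TCP", "aVMCP")) {
        rows[[length(rows) + 1L]] <- data.frame(
          hemisphere_id = hid, sex = c("F", "M")[1 + h %% 2], subtype = st,
          subregion = sr, density = mu_fun(st, sr) + u + rnorm(1, 0, 30))
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("subregion_density_table", "data.frame")
    out
  }
  # exact null: identical expected densities everywhere
  tab0 <- mk_tab(function(st, sr) 1000)
  ct0 <- suppressWarnings(composition_tests(tab0, "within_subregion"))
  for (s in names(ct0)) {
    expect_gt(ct0[[s]]$omnibus$p, 0.01)
    expect_true(all(!ct0[[s]]$pairwise$significant))
    expect_equal(ct0[[s]]$pairwise$p_sidak,
                 sidak_adjust(ct0[[s]]$pairwise$p_raw, 3))
  }
  # forced PV = 2 x SST = 4 x TH: omnibus and all three contrasts significant
  tab1 <- mk_tab(function(st, sr) c(SST = 800, PV = 1600, TH = 400)[[st]])
  ct1 <- suppressWarnings(composition_tests(tab1, "within_subregion"))
  for (s in names(ct1)) {
    expect_lt(ct1[[s]]$omnibus$p, 1e-6)
    expect_true(all(ct1[[s]]$pairwise$significant))
  }
  # two-level factor: Sidak with m = 1 equals the raw p
  tab2 <- tab1[tab1$subtype %in% c("SST", "PV"), ]
  class(tab2) <- c("subregion_density_table", "data.frame")
  ct2 <- suppressWarnings(composition_tests(tab2, "within_subregion"))
  expect_equal(ct2[["DMCP"]]$pairwise$p_sidak, ct2[["DMCP"]]$pairwise$p_raw)
  # the two modes pivot the same table: same strata x factor cell means
  ct_b <- suppressWarnings(composition_tests(tab1, "within_subtype"))
  expect_setequal(names(ct_b), c("SST", "PV", "TH"))
  expect_setequal(names(ct1), c("DMCP", "LCP", "TCP", "aVMCP"))
  expect_equal(sum(vapply(ct_b, function(x) nrow(x$pairwise), integer(1))),
               3L * choose(4, 2))
  # sex interaction variant runs and reports the interaction omnibus
  ct_s <- suppressWarnings(composition_tests(tab1, "within_subregion",
                                             with_sex = TRUE))
  expect_true(all(vapply(ct_s, function(x) is.finite(x$interaction$p),
                         logical(1))))
  # fixed-effects-only fallback agrees on the direction of effects
  ct_f <- composition_tests(tab1, "within_subregion", fixed_only = TRUE)
  expect_lt(ct_f[["LCP"]]$omnibus$p, 1e-6)
  # single-hemisphere stratum errors
  tab_one <- tab1[tab1$hemisphere_id %in% c("SST_h1", "PV_h1", "TH_h1") &
                    tab1$subregion == "DMCP", ]
  tab_one <- tab_one[1, ]
  class(tab_one) <- c("subregion_density_table", "data.frame")
  expect_error(suppressWarnings(composition_tests(tab_one,
                                                  "within_subregion")))
})

test_that("parcel volumes intersect the region mask and cover it exactly", {
  cfg <- tiny_config()
  atlas <- make_toy_atlas(cfg)
  region_vol <- sum(atlas$region$labels == 1L) * (cfg$spacing_um / 1000)^3
  expect_equal(sum(atlas$parcellation$volumes_mm3), region_vol)
  # every labelled parcel voxel lies within the region mask
  expect_true(all(atlas$region$labels[atlas$parcellation$volume$labels != 0L]
                  == 1L))
})
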