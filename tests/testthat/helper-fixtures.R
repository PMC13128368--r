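# Shared fixtures: all built in code, scaled for fast runs.

# Small synthetic configuration (coarse raster, small ellipsoid)
tiny_config <- function(seed = 11L, ...) {
  synthetic_config(seed = seed,
                   semi_axes_mm = c(0.6, 0.5, 0.55),
                   center_mm = c(0, 0.7, 0),
                   spacing_um = 100,
                   subtypes = "TH",
                   baseline = c(TH = 2000),
                   slopes = rbind(TH = c(0, 0, 0)),
                   sex_baseline_offset = c(TH = 0),
                   sex_slope_offset = rbind(TH = c(0, 0, 0)),
                   hemisphere_sd = 0, section_noise_sd = 0,
                   n_animals_per_sex = 1L, ...)
}

# Paper-scale single-subtype configuration used by recovery experiments:
# full-size ellipsoid (27/22/23 analysis planes), 12 hemispheres,
# hemisphere SD 300, section noise SD 400; 75 um raster so generation voxels
# nest exactly in the 150 um analysis planes.
recovery_config <- function(slope_ap = 240, slope_ml = 0, slope_dv = 0,
                            sex_slope_ap = 0, baseline = 2000, seed = 101L,
                            ...) {
  synthetic_config(spacing_um = 75,
                   subtypes = "TH",
                   baseline = c(TH = baseline),
                   slopes = rbind(TH = c(slope_ap, slope_ml, slope_dv)),
                   sex_baseline_offset = c(TH = 0),
                   sex_slope_offset = rbind(TH = c(sex_slope_ap, 0, 0)),
                   hemisphere_sd = 300, section_noise_sd = 400,
                   n_animals_per_sex = 3L, seed = seed, ...)
}

# A deterministic toy label volume: dims, labelled sphere-ish blob
toy_volume <- function(dims = c(12L, 12L, 12L), spacing_um = 100,
                       frame = coordinate_frame(origin_mm = c(0, 0, 0),
                                                axis_signs = c(1, 1, 1)),
                       radius_mm = 0.45) {
  sp <- spacing_um / 1000
  ax <- lapply(dims, function(n) (seq_len(n) - 1) * sp)
  ctr <- (dims - 1) * sp / 2
  lab <- array(0L, dim = dims)
  g <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
  inside <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2 <= radius_mm^2
  lab[inside] <- 1L
  label_volume(lab, spacing_um, frame)
}

# Minimal hand-built cell table
make_cells <- function(ap, ml, dv, subtype = "SST", hemisphere = "A_r",
                       side = "right", sex = "F",
                       animal = sub("_[lr]$", "", hemisphere)) {
  cell_table(data.frame(ap_mm = ap, ml_mm = ml, dv_mm = dv, subtype = subtype,
                        animal_id = animal, hemisphere_id = hemisphere,
                        side = side, sex = sex, stringsAsFactors = FALSE))
}

as_hemi_list <- function(cells) {
  out <- split(as.data.frame(cells), cells$hemisphere_id)
  lapply(out, function(d) { class(d) <- c("cell_table", "data.frame"); d })
}
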