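#' Fit the axis-gradient random-intercept model
#'
#' Density ~ Coordinate + (1 | Hemisphere): observations are the per-
#' hemisphere per-plane raw densities of an axis profile, the coordinate is
#' the plane centre in mm (uncentred, so the slope is in cells/mm^3 per mm
#' along the axis), and hemisphere identity is the random intercept. The
#' slope summarises global directional bias only; it is not meant to capture
#' non-monotonic structure.
#'
#' @param profile an \code{\link{collapse_axis}} result with >= 2 hemispheres
#'   and >= 3 planes.
#' @param method \code{"ML"} (default) or \code{"REML"}.
#' @return an \code{lme_ri} with coefficients \code{"(Intercept)"} and
#'   \code{"coordinate"}, plus attributes \code{axis} and \code{subtype}.
#' @export
fit_axis_gradient <- function(profile, method = "ML") {
  long <- profile_long(profile)
  if (length(unique(long$hemisphere_id)) < 2L)
    stopf("need at least two hemispheres")
  if (length(unique(long$plane_center_mm)) < 3L)
    stopf("need at least three planes")
  X <- cbind("(Intercept)" = 1, coordinate = long$plane_center_mm)
  fit <- fit_random_intercept(long$density, X, long$hemisphere_id,
                              method = method)
  attr(fit, "axis") <- profile$axis
  attr(fit, "subtype") <- profile$subtype
  fit
}

#' Fit the axis gradient with sex main effect and sex-by-coordinate interaction
#'
#' Density ~ Coordinate + Sex + Coordinate x Sex + (1 | Hemisphere), with sex
#' treatment-coded against a female reference, so \code{coordinate} is the
#' female simple slope and \code{coordinate + coordinate:sexM} the male one.
#'
#' @param profile an axis profile whose hemispheres include both sexes.
#' @param method \code{"ML"} or \code{"REML"}.
#' @return list of class \code{axis_sex_fit}: \code{fit} (\code{lme_ri}),
#'   \code{simple_slopes} (per-sex slope, SE), \code{interaction} (the
#'   coordinate-by-sex Wald row).
#' @export
fit_axis_sex_interaction <- function(profile, method = "ML") {
  long <- profile_long(profile)
  if (length(unique(long$sex)) < 2L)
    stopf("both sexes must be present")
  sexM <- as.numeric(long$sex == "M")
  X <- cbind("(Intercept)" = 1, coordinate = long$plane_center_mm,
             sexM = sexM, "coordinate:sexM" = long$plane_center_mm * sexM)
  fit <- fit_random_intercept(long$density, X, long$hemisphere_id,
                              method = method)
  female <- wald_contrast(fit, c(coordinate = 1))
  male <- wald_contrast(fit, c(coordinate = 1, "coordinate:sexM" = 1))
  inter <- wald_contrast(fit, c("coordinate:sexM" = 1))
  out <- list(fit = fit,
              simple_slopes = cbind(sex = c("F", "M"), rbind(female, male)),
              interaction = inter,
              axis = profile$axis, subtype = profile$subtype)
  class(out) <- "axis_sex_fit"
  out
}

#' @export
print.axis_sex_fit <- function(x, ...) {
  cat(sprintf("<axis_sex_fit> %s axis (%s)\n", x$axis, x$subtype))
  cat("simple slopes (cells/mm^3 per mm):\n")
  print(x$simple_slopes, row.names = FALSE)
  cat(sprintf("coordinate x sex: beta = %.3f, se = %.3f, p = %.3g\n",
              x$interaction$estimate, x$interaction$se, x$interaction$p))
  invisible(x)
}

# Observation table at plane or voxel level, for the switchable LME unit.
axis_observations <- function(cells_by_hemisphere, grid, axis,
                              unit = c("plane", "voxel")) {
  unit <- match.arg(unit)
  if (unit == "plane") {
    prof <- collapse_axis(cells_by_hemisphere, grid, axis, n_boot = 0L)
    return(profile_long(prof))
  }
  ax <- axis_index(axis)
  incl <- which(grid$included, arr.ind = TRUE)
  coord <- grid$origin_mm[ax] + (incl[, ax] - 1 + 0.5) * grid$edge_um / 1000
  sex <- hemisphere_sex(cells_by_hemisphere)
  out <- lapply(names(cells_by_hemisphere), function(h) {
    cnt <- voxel_counts(cells_by_hemisphere[[h]], grid)
    data.frame(hemisphere_id = h, sex = unname(sex[h]), axis = axis,
               plane_center_mm = coord,
               density = cnt[grid$included] / grid$voxel_volume_mm3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
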