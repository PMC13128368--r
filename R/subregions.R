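SUBREGION_NAMES <- c("DMCP", "LCP", "TCP", "aVMCP")

#' Parcellation of the region into labelled territories
#'
#' Wraps a parcel label volume (e.g. the four cortical-input-defined
#' caudoputamen territories DMCP/LCP/TCP/aVMCP), optionally intersected with
#' the region mask, and computes per-parcel volumes.
#'
#' @param volume a \code{label_volume} whose nonzero labels are parcels, with
#'   a \code{label_map} naming them.
#' @param region optional region \code{label_volume} on the same raster; if
#'   supplied, parcel labels outside the region mask are zeroed
#'   (the parcellation is masked to the region).
#' @param region_labels labels defining the region mask (default: all
#'   nonzero).
#' @return object of class \code{parcellation}: \code{volume},
#'   \code{volumes_mm3} (named per-parcel volume after intersection).
#' @export
parcellation <- function(volume, region = NULL, region_labels = NULL) {
  labs <- volume$labels
  if (!is.null(region)) {
    if (!frames_equal(volume$frame, region$frame) ||
        abs(volume$spacing_um - region$spacing_um) > 1e-9)
      stopf("parcellation and region are on different rasters")
    rmask <- if (is.null(region_labels)) region$labels != 0L
             else region$labels %in% region_labels
    labs[!rmask] <- 0L
  }
  vv <- (volume$spacing_um / 1000)^3
  codes <- volume$label_map
  volumes_mm3 <- vapply(codes, function(k) sum(labs == k) * vv, numeric(1))
  vol <- volume
  vol$labels <- labs
  structure(list(volume = vol, volumes_mm3 = volumes_mm3),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>\n")
  print(round(x$volumes_mm3, 3))
  invisible(x)
}

#' Assign cells to parcels
#'
#' Per-cell label lookup in the parcellation volume. Cells on unlabelled
#' voxels (or outside the raster) get \code{"unassigned"} and are excluded
#' from subregion densities.
#'
#' @param cells a \code{cell_table}.
#' @param parc a \code{parcellation}.
#' @return the cell table with a \code{subregion} column.
#' @export
assign_subregion <- function(cells, parc) {
  lab <- lookup_labels(parc$volume,
                       as.matrix(cells[, c("ap_mm", "ml_mm", "dv_mm")]))
  nm <- names(parc$volume$label_map)
  code <- unname(parc$volume$label_map)
  cells$subregion <- nm[match(lab, code)]
  cells$subregion[is.na(cells$subregion)] <- "unassigned"
  cells
}

#' Per-hemisphere subregion density table
#'
#' Densities (cells/mm^3) per hemisphere x subregion x subtype: assigned cell
#' count divided by the parcel's (region-masked) volume. Unassigned cells are
#' dropped and counted.
#'
#' @param cells_by_hemisphere list of per-hemisphere \code{cell_table}s
#'   (possibly spanning several subtypes; each table one hemisphere x
#'   subtype).
#' @param parc a \code{parcellation} with strictly positive parcel volumes.
#' @return data.frame (class \code{subregion_density_table}): hemisphere_id,
#'   sex, subtype, subregion, density; attribute \code{n_unassigned}.
#' @export
subregion_density_table <- function(cells_by_hemisphere, parc) {
  if (any(parc$volumes_mm3 <= 0))
    stopf("zero-volume parcel(s): %s",
          paste(names(parc$volumes_mm3)[parc$volumes_mm3 <= 0], collapse = ", "))
  parcels <- names(parc$volumes_mm3)
  n_unassigned <- 0L
  rows <- lapply(cells_by_hemisphere, function(d) {
    d <- assign_subregion(d, parc)
    n_unassigned <<- n_unassigned + sum(d$subregion == "unassigned")
    cnt <- table(factor(d$subregion, levels = parcels))
    data.frame(hemisphere_id = d$hemisphere_id[1], sex = d$sex[1],
               subtype = d$subtype[1], subregion = parcels,
               density = as.numeric(cnt) / unname(parc$volumes_mm3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "n_unassigned") <- n_unassigned
  class(out) <- c("subregion_density_table", "data.frame")
  out
}

#' Sidak family-wise adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m}, clipped to [0, 1]; monotone in both
#' arguments and never below the raw p.
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m number of comparisons in the family (>= 1).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p must lie in [0, 1]")
  if (any(m < 1) || any(m != round(m))) stopf("m must be a positive integer")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Subregion composition tests with Sidak-corrected pairwise contrasts
#'
#' Runs, per stratum, the random-intercept model Density ~ Factor +
#' (1 | Hemisphere): in \code{"within_subregion"} mode the strata are
#' subregions and the factor is subtype (cell-type composition); in
#' \code{"within_subtype"} mode the strata are subtypes and the factor is
#' subregion (regional enrichment). The omnibus test is a joint Wald
#' chi-square on the factor's coefficients; all pairwise level contrasts are
#' Wald tests Sidak-corrected with m = number of pairs. \code{with_sex} adds
#' sex and factor-by-sex fixed effects and an interaction omnibus test.
#'
#' In within-subregion mode each hemisphere carries a single subtype, so the
#' random intercept is confounded with the tested factor; it is retained as
#' specified, and \code{fixed_only = TRUE} gives a fixed-effects-only
#' fallback.
#'
#' @param table a \code{\link{subregion_density_table}}.
#' @param mode \code{"within_subregion"} or \code{"within_subtype"}.
#' @param with_sex add sex and factor x sex fixed effects.
#' @param fixed_only drop the random intercept (plain least squares).
#' @param method \code{"ML"} or \code{"REML"}.
#' @return named list (one element per stratum) of class
#'   \code{composition_tests}; each element has \code{fit}, \code{omnibus},
#'   \code{pairwise} (levels, estimate, se, z, p_raw, p_sidak, significant)
#'   and, with sex, \code{interaction}.
#' @export
composition_tests <- function(table,
                              mode = c("within_subregion", "within_subtype"),
                              with_sex = FALSE, fixed_only = FALSE,
                              method = "ML") {
  mode <- match.arg(mode)
  strat_col <- if (mode == "within_subregion") "subregion" else "subtype"
  fact_col <- if (mode == "within_subregion") "subtype" else "subregion"
  strata <- unique(table[[strat_col]])
  out <- lapply(strata, function(s) {
    d <- table[table[[strat_col]] == s, , drop = FALSE]
    if (length(unique(d$hemisphere_id)) < 2L)
      stopf("stratum %s has a single hemisphere", s)
    lev <- sort(unique(d[[fact_col]]))
    if (length(lev) < 2L)
      stopf("stratum %s has fewer than two %s levels", s, fact_col)
    f <- factor(d[[fact_col]], levels = lev)
    X <- stats::model.matrix(~f)
    colnames(X) <- c("(Intercept)", paste0(fact_col, lev[-1]))
    terms_fact <- colnames(X)[-1]
    if (with_sex) {
      if (length(unique(d$sex)) < 2L)
        stopf("with_sex requires both sexes in stratum %s", s)
      sexM <- as.numeric(d$sex == "M")
      Xint <- X[, -1, drop = FALSE] * sexM
      colnames(Xint) <- paste0(terms_fact, ":sexM")
      X <- cbind(X, sexM = sexM, Xint)
    }
    fit <- if (fixed_only) {
      ols_as_lme_ri(d$density, X)
    } else {
      fit_random_intercept(d$density, X, d$hemisphere_id, method = method)
    }
    omnibus <- wald_joint(fit, terms_fact)
    m <- choose(length(lev), 2L)
    prs <- utils::combn(lev, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- prs[1, k]; b <- prs[2, k]
      wa <- if (a == lev[1]) NULL else stats::setNames(1, paste0(fact_col, a))
      wb <- if (b == lev[1]) NULL else stats::setNames(-1, paste0(fact_col, b))
      ct <- c(wa, wb)
      res <- wald_contrast(fit, ct)
      cbind(data.frame(level_a = a, level_b = b), res)
    }))
    pw$p_sidak <- sidak_adjust(pw$p, m)
    pw$significant <- pw$p_sidak < 0.05
    names(pw)[names(pw) == "p"] <- "p_raw"
    res <- list(stratum = s, fit = fit, omnibus = omnibus, pairwise = pw)
    if (with_sex) {
      res$interaction <- wald_joint(fit, paste0(terms_fact, ":sexM"))
    }
    res
  })
  names(out) <- strata
  class(out) <- "composition_tests"
  attr(out, "mode") <- mode
  out
}

# OLS wrapped in the lme_ri shape (fixed-effects-only fallback)
ols_as_lme_ri <- function(y, X) {
  ols <- stats::lm.fit(X, y)
  res <- ols$residuals
  df <- length(y) - ols$rank
  s2 <- sum(res^2) / df
  R <- qr.R(ols$qr)
  V <- chol2inv(R) * s2
  dimnames(V) <- list(colnames(X), colnames(X))
  out <- list(coefficients = stats::setNames(ols$coefficients, colnames(X)),
              vcov = V, sigma_u2 = 0, sigma_e2 = s2,
              loglik = NA_real_, n_obs = length(y), n_groups = NA_integer_,
              converged = TRUE, singular = FALSE, method = "OLS")
  out$se <- sqrt(diag(V))
  out$z <- out$coefficients / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  class(out) <- "lme_ri"
  out
}

#' @export
print.composition_tests <- function(x, ...) {
  cat(sprintf("<composition_tests> mode = %s\n", attr(x, "mode")))
  for (s in names(x)) {
    cat(sprintf("-- %s: omnibus chisq(%d) = %.2f, p = %.3g\n", s,
                x[[s]]$omnibus$df, x[[s]]$omnibus$chisq, x[[s]]$omnibus$p))
    print(x[[s]]$pairwise[, c("level_a", "level_b", "estimate", "se",
                              "p_raw", "p_sidak", "significant")],
          row.names = FALSE)
  }
  invisible(x)
}
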