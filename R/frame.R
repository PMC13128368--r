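#' Physical coordinate frame of a reference-space raster
#'
#' Defines the affine map between integer raster indices and bregma-relative
#' millimetre coordinates on the (AP, ML, DV) axes. The convention throughout
#' the package is: AP increases anteriorly, ML increases laterally from the
#' midsagittal plane, DV increases ventrally. Raster indices are zero-based,
#' as in reference-space annotation volumes; index (0,0,0) sits at
#' \code{origin_mm}.
#'
#' @param origin_mm numeric 3-vector, mm position (AP, ML, DV) of raster index
#'   (0,0,0). The default places the anterior edge of an Allen-CCF-style raster
#'   at +5.40 mm AP and the lateral index origin 5.70 mm medial of the
#'   midline, so that bregma-relative coordinates come out directly.
#' @param axis_signs integer 3-vector in \{-1, +1\}: sign of the mm coordinate
#'   change per unit index increase along each raster axis.
#' @param midline_ml_mm ML position of the midsagittal plane, in the same
#'   frame coordinates as cell tables (default 0: ML is a signed offset from
#'   the midline, negative on the left).
#' @return an object of class \code{coordinate_frame}.
#' @export
coordinate_frame <- function(origin_mm = c(5.40, -5.70, 0),
                             axis_signs = c(-1L, 1L, 1L),
                             midline_ml_mm = 0) {
  origin_mm <- as.numeric(origin_mm)
  axis_signs <- as.integer(axis_signs)
  if (length(origin_mm) != 3L || anyNA(origin_mm) || any(!is.finite(origin_mm)))
    stopf("origin_mm must be a finite numeric 3-vector")
  if (length(axis_signs) != 3L || !all(axis_signs %in% c(-1L, 1L)))
    stopf("axis_signs must be a 3-vector with entries in {-1, +1}")
  if (length(midline_ml_mm) != 1L || !is.finite(midline_ml_mm))
    stopf("midline_ml_mm must be a finite scalar")
  structure(list(origin_mm = origin_mm, axis_signs = axis_signs,
                 midline_ml_mm = as.numeric(midline_ml_mm)),
            class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat("<coordinate_frame>\n")
  cat(sprintf("  origin (AP, ML, DV):  %s mm\n",
              paste(format(x$origin_mm), collapse = ", ")))
  cat(sprintf("  axis signs:           %s\n",
              paste(x$axis_signs, collapse = ", ")))
  cat(sprintf("  midline ML:           %g mm\n", x$midline_ml_mm))
  invisible(x)
}

is_coordinate_frame <- function(x) inherits(x, "coordinate_frame")

frames_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin_mm - b$origin_mm) < tol) &&
    all(a$axis_signs == b$axis_signs) &&
    abs(a$midline_ml_mm - b$midline_ml_mm) < tol
}

#' Convert raster indices to mm coordinates (and back)
#'
#' \code{index_to_mm} maps zero-based raster indices to frame mm coordinates
#' of the voxel centre; \code{mm_to_index} is its inverse, flooring to the
#' containing voxel (half-open voxel intervals centred on the index).
#'
#' @param volume a \code{label_volume} (or any list with \code{frame} and
#'   \code{spacing_um} fields).
#' @param index integer matrix (n x 3) or 3-vector of zero-based indices.
#' @param mm numeric matrix (n x 3) or 3-vector of mm coordinates.
#' @return \code{index_to_mm}: an n x 3 matrix of mm coordinates;
#'   \code{mm_to_index}: an n x 3 integer matrix of zero-based indices.
#' @export
index_to_mm <- function(volume, index) {
  index <- rbind_vec(index)
  dims <- dim(volume$labels)
  if (any(index < 0L) || any(sweep(index, 2, dims, ">=")))
    stopf("raster index out of range")
  sp <- volume$spacing_um / 1000
  fr <- volume$frame
  sweep(sweep(index, 2, fr$axis_signs * sp, "*"), 2, fr$origin_mm, "+")
}

#' @rdname index_to_mm
#' @export
mm_to_index <- function(volume, mm) {
  mm <- rbind_vec(mm)
  sp <- volume$spacing_um / 1000
  fr <- volume$frame
  u <- sweep(sweep(mm, 2, fr$origin_mm, "-"), 2, fr$axis_signs / sp, "*")
  idx <- floor(u + 0.5)
  storage.mode(idx) <- "integer"
  idx
}

rbind_vec <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}
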