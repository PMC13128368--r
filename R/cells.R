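CELL_SUBTYPES <- c("SST", "PV", "TH")
CELL_COLUMNS <- c("ap_mm", "ml_mm", "dv_mm", "subtype", "animal_id",
                  "hemisphere_id", "side", "sex")

#' Construct and validate a cell table
#'
#' One row per detected soma: bregma-relative mm coordinates (AP anterior+,
#' ML lateral+ from midline, DV ventral+), interneuron subtype, and animal /
#' hemisphere / sex metadata. \code{hemisphere_id} must identify a unique
#' (animal, side) pair — the hemisphere is the independent sampling unit for
#' the bootstrap and the mixed models.
#'
#' @param df data.frame with columns \code{ap_mm}, \code{ml_mm}, \code{dv_mm},
#'   \code{subtype}, \code{animal_id}, \code{hemisphere_id}, \code{side},
#'   \code{sex}.
#' @return the validated data.frame with class \code{cell_table}.
#' @export
cell_table <- function(df) {
  missing_cols <- setdiff(CELL_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stopf("cell table is missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, CELL_COLUMNS, drop = FALSE]
  for (cc in c("ap_mm", "ml_mm", "dv_mm")) {
    df[[cc]] <- as.numeric(df[[cc]])
    nbad <- sum(!is.finite(df[[cc]]))
    if (nbad > 0L)
      stopf("%d row(s) with missing/unparseable %s", nbad, cc)
  }
  for (cc in c("subtype", "animal_id", "hemisphere_id", "side", "sex"))
    df[[cc]] <- as.character(df[[cc]])
  if (!all(df$subtype %in% CELL_SUBTYPES))
    stopf("subtype must be one of %s", paste(CELL_SUBTYPES, collapse = "/"))
  if (!all(df$side %in% c("left", "right")))
    stopf("side must be 'left' or 'right'")
  if (!all(df$sex %in% c("M", "F"))) stopf("sex must be 'M' or 'F'")
  key <- paste(df$animal_id, df$side, sep = "\r")
  hk <- unique(paste(df$hemisphere_id, key, sep = "\r"))
  if (length(hk) != length(unique(df$hemisphere_id)))
    stopf("hemisphere_id does not map to a unique (animal_id, side)")
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a per-cell coordinate CSV
#'
#' @param path CSV file path.
#' @param columns named character vector mapping canonical column names
#'   (\code{ap_mm}, \code{ml_mm}, ...) to file column names; unlisted columns
#'   are assumed to carry their canonical names.
#' @param units \code{"mm"} (default) or \code{"um"}; with \code{"um"} the
#'   three coordinates are divided by 1000 on read.
#' @return a \code{\link{cell_table}}.
#' @export
read_cells <- function(path, columns = NULL, units = c("mm", "um")) {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("file not found: %s", path)
  # read everything as character ("F" sex codes would otherwise parse as
  # logical); cell_table() retypes the coordinates
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  map <- stats::setNames(CELL_COLUMNS, CELL_COLUMNS)
  if (!is.null(columns)) map[names(columns)] <- unlist(columns)
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0L)
    stopf("CSV %s lacks mapped columns: %s", path,
          paste(missing_cols, collapse = ", "))
  df <- stats::setNames(raw[, unname(map), drop = FALSE], names(map))
  if (units == "um")
    for (cc in c("ap_mm", "ml_mm", "dv_mm")) df[[cc]] <- as.numeric(df[[cc]]) / 1000
  cell_table(df)
}

#' Write a cell table to CSV with canonical column names
#' @param cells a \code{cell_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(as.data.frame(cells)[, CELL_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only cells inside a labelled region
#'
#' Per-cell raster label lookup: a cell is kept iff its containing raster
#' voxel carries one of the listed labels. Idempotent; an empty result is
#' allowed.
#'
#' @param cells a \code{cell_table}.
#' @param region a \code{label_volume}.
#' @param region_labels label codes to keep.
#' @param quiet suppress the removed-count message.
#' @return the filtered \code{cell_table}.
#' @export
filter_to_region <- function(cells, region, region_labels, quiet = FALSE) {
  lab <- lookup_labels(region, as.matrix(cells[, c("ap_mm", "ml_mm", "dv_mm")]))
  keep <- !is.na(lab) & lab %in% region_labels
  if (!quiet)
    message(sprintf("filter_to_region: removed %d of %d cells",
                    sum(!keep), length(keep)))
  out <- cells[keep, , drop = FALSE]
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Reflect left-hemisphere cells across the midline
#'
#' For rows with \code{side == "left"}, \code{ml <- 2 * midline - ml}; right
#' rows (and cells exactly on the midline, which are treated as right) are
#' untouched. The side label is preserved so hemisphere identity remains
#' available for lateralization analyses. Applying the operation twice
#' returns the original table (involution).
#'
#' @param cells a \code{cell_table}.
#' @param frame a \code{coordinate_frame} supplying \code{midline_ml_mm}.
#' @return the mirrored \code{cell_table}.
#' @export
mirror_left_to_right <- function(cells, frame) {
  if (!"side" %in% names(cells) || anyNA(cells$side))
    stopf("cells must carry a complete 'side' column")
  is_left <- cells$side == "left"
  cells$ml_mm[is_left] <- 2 * frame$midline_ml_mm - cells$ml_mm[is_left]
  cells
}

# Split a cell table into its per-hemisphere tables (named list)
split_hemispheres <- function(cells) {
  out <- split(as.data.frame(cells), cells$hemisphere_id)
  lapply(out, function(d) { class(d) <- c("cell_table", "data.frame"); d })
}

hemisphere_sex <- function(cells_by_hemisphere) {
  vapply(cells_by_hemisphere, function(d) d$sex[1], character(1))
}
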