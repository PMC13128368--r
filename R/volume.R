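#' Integer label volume in a reference coordinate frame
#'
#' A 3D integer raster (region annotations or parcel IDs) with isotropic
#' spacing and a \code{\link{coordinate_frame}}. Axis order is (AP, ML, DV).
#'
#' @param labels 3D integer array.
#' @param spacing_um isotropic voxel edge of the raster, in micrometres.
#' @param frame a \code{coordinate_frame}.
#' @param label_map named integer vector mapping region names to label codes;
#'   if \code{NULL}, one is derived from the nonzero labels present.
#' @return an object of class \code{label_volume}.
#' @export
label_volume <- function(labels, spacing_um, frame = coordinate_frame(),
                         label_map = NULL) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3D array")
  if (length(labels) == 0L) stopf("labels raster is empty")
  if (is.double(labels)) {
    if (any(labels != round(labels), na.rm = TRUE))
      stopf("labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stopf("labels must be integer-valued")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stopf("spacing_um must be a positive scalar")
  if (!is_coordinate_frame(frame)) stopf("frame must be a coordinate_frame")
  if (is.null(label_map)) {
    codes <- sort(setdiff(unique(as.vector(labels)), 0L))
    label_map <- stats::setNames(codes, paste0("label_", codes))
  }
  structure(list(labels = labels, spacing_um = as.numeric(spacing_um),
                 frame = frame, label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s raster, %g um spacing, %d nonzero labels\n",
              paste(dim(x$labels), collapse = " x "), x$spacing_um,
              length(x$label_map)))
  invisible(x)
}

#' Load a label volume from NRRD or NIfTI-1
#'
#' Reads a 3D integer raster. Spacing is taken from the file header
#' (\code{spacings}/\code{space directions} for NRRD, \code{pixdim} for
#' NIfTI); the data axis order is assumed already reconciled to (AP, ML, DV)
#' as declared by \code{frame}.
#'
#' @param path file path (\code{.nrrd}, \code{.nhdr}, \code{.nii},
#'   \code{.nii.gz}).
#' @param format one of \code{"auto"}, \code{"nrrd"}, \code{"nifti"}.
#' @param frame the \code{coordinate_frame} the raster lives in.
#' @param label_map optional named integer vector of region names.
#' @return a \code{\link{label_volume}}.
#' @export
load_label_volume <- function(path, format = c("auto", "nrrd", "nifti"),
                              frame = coordinate_frame(), label_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE))
      "nifti" else "nrrd"
  }
  if (format == "nrrd") {
    nr <- read_nrrd(path)
    arr <- nr$data
    spacing_um <- nr$spacing_mm * 1000
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    spacing_um <- RNifti::pixdim(img)[1] * 1000
  }
  if (length(dim(arr)) != 3L) stopf("%s: expected a 3D raster", path)
  if (any(arr != round(arr), na.rm = TRUE))
    stopf("%s: raster is not integer-valued", path)
  storage.mode(arr) <- "integer"
  label_volume(arr, spacing_um = spacing_um, frame = frame,
               label_map = label_map)
}

# ---- minimal NRRD0004 I/O ---------------------------------------------------
# Supports: 3D rasters, encodings raw (little-endian) and ascii, attached or
# detached (.nhdr + data file) headers, types uchar/short/ushort/int/uint/
# float/double. Spacing read from "spacings" or diagonal "space directions".

nrrd_types <- list(
  uchar  = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
  short  = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
  ushort = list(what = "integer", size = 2L, signed = FALSE, mode = "integer"),
  int    = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  uint   = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  float  = list(what = "double",  size = 4L, signed = TRUE,  mode = "double"),
  double = list(what = "double",  size = 8L, signed = TRUE,  mode = "double")
)

normalize_nrrd_type <- function(type) {
  aliases <- c("unsigned char" = "uchar", "uint8" = "uchar", "uint8_t" = "uchar",
               "signed short" = "short", "short int" = "short", "int16" = "short",
               "int16_t" = "short", "unsigned short" = "ushort", "uint16" = "ushort",
               "uint16_t" = "ushort", "signed int" = "int", "int32" = "int",
               "int32_t" = "int", "unsigned int" = "uint", "uint32" = "uint",
               "uint32_t" = "uint")
  type <- trimws(type)
  if (type %in% names(aliases)) type <- aliases[[type]]
  if (!type %in% names(nrrd_types)) stopf("unsupported NRRD type: %s", type)
  type
}

#' Read an NRRD raster
#'
#' @param path path to a \code{.nrrd} file or detached \code{.nhdr} header.
#' @return list with \code{data} (array), \code{spacing_mm} (scalar) and
#'   \code{header} (named character vector).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stopf("%s: not an NRRD file", path)
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    header[key] <- val
  }
  if (!all(c("type", "dimension", "sizes", "encoding") %in% names(header)))
    stopf("%s: incomplete NRRD header", path)
  ndim <- as.integer(header["dimension"])
  sizes <- as.integer(strsplit(header["sizes"], "\\s+")[[1]])
  if (length(sizes) != ndim) stopf("%s: sizes/dimension mismatch", path)
  type <- normalize_nrrd_type(header["type"])
  tp <- nrrd_types[[type]]
  n <- prod(sizes)
  encoding <- tolower(header["encoding"])
  endian <- tolower(header["endian"] %||% "little")

  data_con <- con
  if ("data file" %in% names(header) || "datafile" %in% names(header)) {
    df <- if ("data file" %in% names(header)) header[["data file"]] else header[["datafile"]]
    dpath <- file.path(dirname(path), df)
    if (!file.exists(dpath)) stopf("detached NRRD data file not found: %s", dpath)
    data_con <- file(dpath, "rb")
    on.exit(close(data_con), add = TRUE)
  }
  if (encoding == "raw") {
    vals <- readBin(data_con, what = tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = endian)
  } else if (encoding %in% c("ascii", "txt", "text")) {
    txt <- readLines(data_con, warn = FALSE)
    vals <- as.numeric(scan(text = paste(txt, collapse = " "), quiet = TRUE))
    if (tp$mode == "integer") storage.mode(vals) <- "integer"
  } else {
    stopf("%s: unsupported NRRD encoding '%s'", path, encoding)
  }
  if (length(vals) != n) stopf("%s: truncated NRRD data", path)
  data <- array(vals, dim = sizes)

  spacing_mm <- NA_real_
  if ("spacings" %in% names(header)) {
    sp <- as.numeric(strsplit(header["spacings"], "\\s+")[[1]])
    spacing_mm <- sp[1]
  } else if ("space directions" %in% names(header)) {
    vecs <- regmatches(header["space directions"],
                       gregexpr("\\(([^)]*)\\)", header["space directions"]))[[1]]
    if (length(vecs) >= 1L) {
      v1 <- as.numeric(strsplit(gsub("[()]", "", vecs[1]), ",")[[1]])
      spacing_mm <- sqrt(sum(v1^2))
    }
  }
  list(data = data, spacing_mm = spacing_mm, header = header)
}

#' Write an array as NRRD
#'
#' @param x numeric or integer array (up to 3D).
#' @param path output path.
#' @param spacing_mm isotropic voxel spacing written to the header, mm.
#' @param encoding \code{"raw"} (little-endian) or \code{"ascii"}.
#' @return \code{path}, invisibly.
#' @export
write_nrrd <- function(x, path, spacing_mm = NA_real_,
                       encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  dims <- dim(x) %||% length(x)
  type <- if (is.integer(x)) "int" else "double"
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           paste0("dimension: ", length(dims)),
           paste0("sizes: ", paste(dims, collapse = " ")),
           paste0("encoding: ", encoding))
  if (encoding == "raw") hdr <- c(hdr, "endian: little")
  if (!is.na(spacing_mm))
    hdr <- c(hdr, paste0("spacings: ",
                         paste(rep(format(spacing_mm, digits = 12), length(dims)),
                               collapse = " ")))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, ""), con)
  if (encoding == "raw") {
    writeBin(as.vector(x), con, size = if (type == "int") 4L else 8L,
             endian = "little")
  } else {
    writeLines(paste(format(as.vector(x), digits = 17, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Write a label volume to NRRD
#' @param volume a \code{label_volume}.
#' @param path output path.
#' @param encoding NRRD encoding.
#' @return \code{path}, invisibly.
#' @export
write_label_volume <- function(volume, path, encoding = c("raw", "ascii")) {
  write_nrrd(volume$labels, path, spacing_mm = volume$spacing_um / 1000,
             encoding = match.arg(encoding))
}

# Label under each mm coordinate (NA outside the raster)
lookup_labels <- function(volume, coords_mm) {
  idx <- mm_to_index(volume, coords_mm)
  dims <- dim(volume$labels)
  ok <- idx[, 1] >= 0L & idx[, 1] < dims[1] &
        idx[, 2] >= 0L & idx[, 2] < dims[2] &
        idx[, 3] >= 0L & idx[, 3] < dims[3]
  out <- rep(NA_integer_, nrow(idx))
  if (any(ok)) out[ok] <- volume$labels[idx[ok, , drop = FALSE] + 1L]
  out
}
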