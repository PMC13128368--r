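`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
axis_index <- function(axis) {
  ax <- match.arg(toupper(axis), c("AP", "ML", "DV"))
  c(AP = 1L, ML = 2L, DV = 3L)[[ax]]
}

# Recursively merge y into x (y wins on leaves)
modify_list_deep <- function(x, y) {
  for (nm in names(y)) {
    if (is.list(y[[nm]]) && is.list(x[[nm]]) && !is.null(names(y[[nm]]))) {
      x[[nm]] <- modify_list_deep(x[[nm]], y[[nm]])
    } else {
      x[[nm]] <- y[[nm]]
    }
  }
  x
}
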