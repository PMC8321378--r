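#' Label masks for optic disc and cup
#'
#' A `label_mask` is an integer matrix with one row per image row and values
#' `0` (background), `1` (neuroretinal rim, i.e. disc outside the cup) and
#' `2` (optic cup).  The disc region is the union of labels 1 and 2.  On
#' construction the cup is forced inside the disc: any pixel marked as cup
#' but not as disc is relabelled to disc (rim) and a warning is emitted, so
#' the containment invariant cup subset-of disc always holds afterwards.
#'
#' @param disc logical or 0/1 matrix marking the full disc region (cup
#'   included), or an integer label matrix already in the 0/1/2 scheme when
#'   `cup` is missing.
#' @param cup logical or 0/1 matrix marking the cup region; same dimensions
#'   as `disc`.
#' @return An object of class `label_mask`: an integer matrix in the 0/1/2
#'   scheme.
#' @examples
#' disc <- matrix(FALSE, 32, 32); disc[8:24, 8:24] <- TRUE
#' cup <- matrix(FALSE, 32, 32); cup[12:20, 12:20] <- TRUE
#' m <- label_mask(disc, cup)
#' table(m)
#' @export
label_mask <- function(disc, cup = NULL) {
  if (is.null(cup)) {
    lab <- disc
    if (!is.matrix(lab)) abort_input("label matrix expected")
    bad <- !(lab %in% 0:2)
    if (any(bad)) abort_input("label values must be 0, 1 or 2")
    m <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  } else {
    disc <- disc_as_logical(disc)
    cup <- disc_as_logical(cup)
    if (!identical(dim(disc), dim(cup))) {
      abort_input("disc and cup masks must have identical dimensions")
    }
    outside <- cup & !disc
    if (any(outside)) {
      warn_spagen(sprintf(
        "%d cup pixel(s) outside the disc relabelled to disc",
        sum(outside)), "spagen_clip_warning")
    }
    m <- matrix(0L, nrow(disc), ncol(disc))
    m[disc | cup] <- 1L            # rim (or clipped cup)
    m[cup & disc] <- 2L
  }
  if (!any(m > 0L)) abort_degenerate("mask has no disc pixels")
  structure(m, class = c("label_mask", "matrix", "array"))
}

disc_as_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  abort_input("mask must be logical or numeric")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %d x %d: %d disc px (%d cup)>\n",
              nrow(x), ncol(x), sum(x > 0L), sum(x == 2L)))
  invisible(x)
}

disc_region <- function(mask) unclass(mask) > 0L
cup_region <- function(mask) unclass(mask) == 2L

#' Read a cup/disc label mask from a raster file
#'
#' Reads a PNG or TIFF label image and normalizes it to the 0/1/2 scheme of
#' [label_mask()].  Grayscale encodings such as `{0, 128, 255}` are handled
#' through `encoding`, a length-3 vector of the raw 8-bit values that stand
#' for background, disc and cup.  Multi-channel images are collapsed to
#' their first channel.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param encoding raw pixel values (0--255) coding background, disc and cup,
#'   in that order.  Default `c(0, 1, 2)`.
#' @return A [label_mask()].
#' @export
load_mask <- function(path, encoding = c(0, 1, 2)) {
  if (!file.exists(path)) abort_io(sprintf("cannot read mask file '%s'", path))
  raw <- read_raster(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  vals <- as.integer(round(raw * 255))
  if (length(encoding) != 3L) abort_input("encoding must have 3 values")
  lab <- matrix(NA_integer_, nrow(raw), ncol(raw))
  for (k in 1:3) lab[vals == as.integer(encoding[k])] <- k - 1L
  if (anyNA(lab)) {
    abort_input(sprintf(
      "mask contains pixel values outside the encoding {%s}: saw {%s}",
      paste(encoding, collapse = ", "),
      paste(utils::head(setdiff(unique(vals), encoding), 5), collapse = ", ")))
  }
  if (!any(lab > 0L)) abort_degenerate(sprintf("mask '%s' has no disc pixels", path))
  label_mask(lab)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_io(sprintf("unsupported raster format '.%s'", ext))),
    error = function(e) {
      if (inherits(e, "spagen_error")) stop(e)
      abort_io(sprintf("cannot decode raster '%s': %s", path,
                       conditionMessage(e)))
    })
}

#' Write a label mask (or RGB image) as PNG
#'
#' @param x a [label_mask()] or a numeric `H x W x 3` array in `[0, 1]`.
#' @param path output path ending in `.png`.
#' @param encoding raw values used for background/disc/cup when `x` is a
#'   label mask.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, encoding = c(0, 1, 2)) {
  if (inherits(x, "label_mask")) {
    img <- matrix(encoding[unclass(x) + 1L] / 255, nrow(x), ncol(x))
  } else {
    img <- x
  }
  png::writePNG(img, path)
  invisible(path)
}
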