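#' Read a grayscale image
#'
#' Accepts 8- or 16-bit PNG and 8-bit JPEG. Output is a single-channel
#' numeric matrix scaled to `[0,1]` (8-bit values divided by 255, 16-bit by
#' 65535 — both handled natively by the readers). RGB input is converted to
#' luminance (Rec. 601: 0.299 R + 0.587 G + 0.114 B).
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric matrix (rows = image rows, origin top-left).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_ctrseg(sprintf("image file '%s' does not exist", path), "ctrseg_io_error")
  }
  kind <- sniff_format(path)
  x <- switch(kind,
    png = png::readPNG(path),
    jpeg = jpeg::readJPEG(path),
    stop_ctrseg(sprintf("'%s' is neither PNG nor JPEG", path), "ctrseg_format_error")
  )
  to_gray(x)
}

sniff_format <- function(path) {
  magic <- readBin(path, "raw", n = 3L)
  if (length(magic) >= 3 && identical(magic[1:3], as.raw(c(0x89, 0x50, 0x4e)))) return("png")
  if (length(magic) >= 2 && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) return("jpeg")
  "unknown"
}

to_gray <- function(x) {
  if (length(dim(x)) == 2) return(x)
  if (dim(x)[3] == 2) return(x[, , 1])          # gray + alpha
  if (dim(x)[3] >= 3) {
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  }
  x[, , 1]
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image numeric matrix in `[0,1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read / write a label mask
#'
#' Masks are per-pixel class maps over \{0 = background, 1 = lung,
#' 2 = heart\}, stored losslessly as PNG (grayscale with literal class
#' values, or palette PNG with indices 0/1/2 — palettes are expanded by the
#' reader and re-validated). JPEG is rejected outright: lossy compression
#' corrupts labels. Any value outside \{0,1,2\} raises a validation error
#' naming the offending value; readers never silently relabel.
#'
#' @param path path to a mask PNG.
#' @return integer matrix with values in \{0,1,2\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop_ctrseg(sprintf("mask file '%s' does not exist", path), "ctrseg_io_error")
  }
  kind <- sniff_format(path)
  if (kind == "jpeg") {
    stop_ctrseg("masks must be PNG; JPEG is lossy and corrupts class labels",
                "ctrseg_format_error")
  }
  if (kind != "png") {
    stop_ctrseg(sprintf("'%s' is not a PNG file", path), "ctrseg_format_error")
  }
  x <- png::readPNG(path)
  x <- to_gray(x)
  as_label_mask(x * 255)
}

as_label_mask <- function(x) {
  v <- round(x)
  if (max(abs(x - v)) > 1e-6 || any(!v %in% c(0, 1, 2))) {
    bad <- unique(round(x[!round(x) %in% c(0, 1, 2) | abs(x - round(x)) > 1e-6], 3))
    stop_ctrseg(sprintf("mask contains value(s) outside {0,1,2}: %s",
                        paste(head(bad, 5), collapse = ", ")),
                "ctrseg_validation_error")
  }
  storage.mode(v) <- "integer"
  v
}

#' @param mask integer matrix with values in \{0,1,2\}.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  mask <- as_label_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read / write a sample manifest
#'
#' The manifest is a CSV with header `image_path,mask_path,true_ctr,seed`
#' (reference columns may be absent for prediction-only manifests). Paths are
#' interpreted relative to the manifest's directory when not absolute.
#'
#' @param path manifest CSV path.
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"image_path" %in% names(m)) {
    stop_ctrseg("manifest must have an image_path column", "ctrseg_format_error")
  }
  base <- dirname(path)
  fix <- function(p) ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  if ("mask_path" %in% names(m)) m$mask_path <- fix(m$mask_path)
  tibble::as_tibble(m)
}

# boundary pixels of a one-vs-rest region: region pixels with a 4-neighbour
# outside the region (or on the image border)
region_boundary <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- bin
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  bin & !inner
}

#' Render a contour overlay
#'
#' Draws class contours over the grayscale image and writes a PNG: predicted
#' heart and lung contours in blue, reference heart in red and reference lung
#' in orange. Either mask may be omitted. Pure visualization; the only
#' product is the written file.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param pred_mask,ref_mask optional label masks of the same size.
#' @param out output PNG path.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(image, pred_mask = NULL, ref_mask = NULL, out) {
  for (m in list(pred_mask, ref_mask)) {
    if (!is.null(m) && !all(dim(m) == dim(image))) {
      stop_ctrseg("mask and image dimensions differ", "ctrseg_parameter_error")
    }
  }
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), c(dim(image), 3))
  paint <- function(rgb, where, col) {
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[where] <- col[ch]
      rgb[, , ch] <- plane
    }
    rgb
  }
  if (!is.null(ref_mask)) {
    rgb <- paint(rgb, region_boundary(ref_mask == 1L), c(1.0, 0.55, 0.0))  # lung: orange
    rgb <- paint(rgb, region_boundary(ref_mask == 2L), c(1.0, 0.0, 0.0))   # heart: red
  }
  if (!is.null(pred_mask)) {
    rgb <- paint(rgb, region_boundary(pred_mask == 1L) | region_boundary(pred_mask == 2L),
                 c(0.1, 0.3, 1.0))                                          # predicted: blue
  }
  png::writePNG(rgb, out)
  invisible(out)
}
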