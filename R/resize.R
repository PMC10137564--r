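#' Resize a grayscale raster or a label mask
#'
#' Images are resampled bilinearly; label masks use nearest-neighbour
#' resampling so that no interpolated (non-existent) class values can appear.
#' The pixel-centre mapping `src = (dst + 0.5) * size_in/size_out - 0.5` is
#' used for both, so integer upscaling followed by downscaling back to the
#' original grid is the identity on labels.
#'
#' @param x numeric matrix (image in `[0,1]`) or integer matrix (mask).
#' @param height_px,width_px target dimensions.
#' @return matrix of size `height_px x width_px`.
#' @export
resize_image <- function(x, height_px, width_px) {
  resample_grid(x, height_px, width_px, method = "bilinear")
}

#' @rdname resize_image
#' @export
resize_mask <- function(x, height_px, width_px) {
  out <- resample_grid(x, height_px, width_px, method = "nearest")
  storage.mode(out) <- "integer"
  out
}

resample_grid <- function(x, height_px, width_px, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(x); W <- ncol(x)
  check_count(height_px, "height_px"); check_count(width_px, "width_px")
  if (H == height_px && W == width_px) return(x)
  sr <- (seq_len(height_px) - 0.5) * H / height_px - 0.5
  sc <- (seq_len(width_px) - 0.5) * W / width_px - 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(sr + 1e-9), 0), H - 1) + 1
    ci <- pmin(pmax(round(sc + 1e-9), 0), W - 1) + 1
    return(x[ri, ci, drop = FALSE])
  }
  r0 <- pmin(pmax(floor(sr), 0), H - 1)
  c0 <- pmin(pmax(floor(sc), 0), W - 1)
  r1 <- pmin(r0 + 1, H - 1)
  c1 <- pmin(c0 + 1, W - 1)
  fr <- pmin(pmax(sr - r0, 0), 1)
  fc <- pmin(pmax(sc - c0, 0), 1)
  a00 <- x[r0 + 1, c0 + 1, drop = FALSE]
  a10 <- x[r1 + 1, c0 + 1, drop = FALSE]
  a01 <- x[r0 + 1, c1 + 1, drop = FALSE]
  a11 <- x[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, height_px, width_px)
  wc <- matrix(fc, height_px, width_px, byrow = TRUE)
  (a00 * (1 - wr) + a10 * wr) * (1 - wc) + (a01 * (1 - wr) + a11 * wr) * wc
}

# Sample x at fractional (row, col) coordinates (1-based matrices of equal
# size). Bilinear for images, nearest for masks; out-of-domain coordinates map
# to `fill`.
warp_sample <- function(x, src_r, src_c, method = c("bilinear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  H <- nrow(x); W <- ncol(x)
  outside <- src_r < 1 | src_r > H | src_c < 1 | src_c > W
  if (method == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), H)
    ci <- pmin(pmax(round(src_c), 1), W)
    out <- x[cbind(as.vector(ri), as.vector(ci))]
  } else {
    r0 <- pmin(pmax(floor(src_r), 1), H); r1 <- pmin(r0 + 1, H)
    c0 <- pmin(pmax(floor(src_c), 1), W); c1 <- pmin(c0 + 1, W)
    fr <- pmin(pmax(src_r - r0, 0), 1)
    fc <- pmin(pmax(src_c - c0, 0), 1)
    v00 <- x[cbind(as.vector(r0), as.vector(c0))]
    v10 <- x[cbind(as.vector(r1), as.vector(c0))]
    v01 <- x[cbind(as.vector(r0), as.vector(c1))]
    v11 <- x[cbind(as.vector(r1), as.vector(c1))]
    out <- (v00 * (1 - fr) + v10 * fr) * (1 - fc) + (v01 * (1 - fr) + v11 * fr) * fc
  }
  out[as.vector(outside)] <- fill
  out <- matrix(out, nrow(src_r), ncol(src_r))
  if (method == "nearest") storage.mode(out) <- storage.mode(x)
  out
}
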