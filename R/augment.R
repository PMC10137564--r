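#' Data augmentation configuration
#'
#' The battery covers seven transforms: random resized crop,
#' shift/scale/rotate, random brightness/contrast, image inversion, elastic
#' transform, grid distortion and optical (radial) distortion. Geometric
#' transforms are applied identically to image and mask; the mask is always
#' resampled nearest-neighbour so no interpolated class labels can appear.
#' Photometric transforms (brightness/contrast, inversion) touch the image
#' only.
#'
#' @param enabled character vector of transform names to enable (any subset
#'   of the seven listed above).
#' @param p per-transform application probability.
#' @param crop_scale range of area fractions for the random resized crop.
#' @param crop_ratio range of aspect-ratio multipliers for the crop.
#' @param shift_limit,scale_limit,rotate_limit_deg magnitudes for
#'   shift/scale/rotate (fraction of size, fraction, degrees).
#' @param brightness_limit,contrast_limit photometric magnitudes.
#' @param elastic_alpha_px,elastic_sigma_px displacement amplitude and
#'   smoothing of the elastic field, pixels.
#' @param grid_steps,grid_limit grid distortion cells per axis and relative
#'   step perturbation.
#' @param optical_limit radial distortion coefficient range.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(enabled = c("random_resized_crop", "shift_scale_rotate",
                                       "random_brightness_contrast", "invert",
                                       "elastic_transform", "grid_distortion",
                                       "optical_distortion"),
                           p = 0.5,
                           crop_scale = c(0.7, 1.0), crop_ratio = c(0.9, 1.1),
                           shift_limit = 0.0625, scale_limit = 0.1,
                           rotate_limit_deg = 15,
                           brightness_limit = 0.2, contrast_limit = 0.2,
                           elastic_alpha_px = 8, elastic_sigma_px = 6,
                           grid_steps = 4L, grid_limit = 0.2,
                           optical_limit = 0.25) {
  all_tf <- c("random_resized_crop", "shift_scale_rotate",
              "random_brightness_contrast", "invert", "elastic_transform",
              "grid_distortion", "optical_distortion")
  bad <- setdiff(enabled, all_tf)
  if (length(bad) > 0) {
    stop_ctrseg(paste0("unknown transform(s): ", paste(bad, collapse = ", ")),
                "ctrseg_parameter_error")
  }
  check_number(p, "p", 0, 1)
  structure(list(enabled = enabled, p = p, crop_scale = crop_scale,
                 crop_ratio = crop_ratio, shift_limit = shift_limit,
                 scale_limit = scale_limit, rotate_limit_deg = rotate_limit_deg,
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 elastic_alpha_px = elastic_alpha_px,
                 elastic_sigma_px = elastic_sigma_px,
                 grid_steps = as.integer(grid_steps), grid_limit = grid_limit,
                 optical_limit = optical_limit),
            class = "augment_config")
}

#' Augmentation disabled
#' @return an `augment_config` with no transforms enabled.
#' @export
augment_none <- function() augment_config(enabled = character())

#' Apply the augmentation battery to an image/mask pair
#'
#' Deterministic for a fixed seed. Geometric warps use one shared coordinate
#' field for image (bilinear) and mask (nearest-neighbour); out-of-frame
#' regions become intensity 0 / background.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param mask integer label mask of the same size.
#' @param cfg an [augment_config()].
#' @param seed integer seed.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, cfg, seed) {
  stopifnot(inherits(cfg, "augment_config"))
  if (!all(dim(image) == dim(mask))) {
    stop_ctrseg("image and mask sizes differ", "ctrseg_shape_error")
  }
  if (length(cfg$enabled) == 0) return(list(image = image, mask = mask))
  with_seed(seed, augment_impl(image, mask, cfg))
}

augment_impl <- function(image, mask, cfg) {
  H <- nrow(image); W <- ncol(image)
  on_tf <- function(nm) nm %in% cfg$enabled && runif(1) < cfg$p

  grid_rc <- function() {
    list(r = matrix(seq_len(H), H, W), c = matrix(seq_len(W), H, W, byrow = TRUE))
  }
  apply_warp <- function(src) {
    image <<- warp_sample(image, src$r, src$c, "bilinear", fill = 0)
    mask <<- warp_sample(mask, src$r, src$c, "nearest", fill = 0L)
  }

  if (on_tf("random_resized_crop")) {
    area <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
    ratio <- runif(1, cfg$crop_ratio[1], cfg$crop_ratio[2])
    ch <- min(H, round(H * sqrt(area / ratio)))
    cw <- min(W, round(W * sqrt(area * ratio)))
    r0 <- sample.int(H - ch + 1L, 1L) - 1L
    c0 <- sample.int(W - cw + 1L, 1L) - 1L
    src <- list(r = matrix(r0 + (seq_len(H) - 0.5) * ch / H + 0.5, H, W),
                c = matrix(c0 + (seq_len(W) - 0.5) * cw / W + 0.5, H, W, byrow = TRUE))
    apply_warp(src)
  }
  if (on_tf("shift_scale_rotate")) {
    dx <- runif(1, -1, 1) * cfg$shift_limit * W
    dy <- runif(1, -1, 1) * cfg$shift_limit * H
    sc <- 1 + runif(1, -1, 1) * cfg$scale_limit
    th <- runif(1, -1, 1) * cfg$rotate_limit_deg * pi / 180
    g <- grid_rc()
    yc <- g$r - (H + 1) / 2 - dy
    xc <- g$c - (W + 1) / 2 - dx
    # inverse map: rotate by -th, scale by 1/sc
    src <- list(r = (cos(th) * yc - sin(th) * xc) / sc + (H + 1) / 2,
                c = (sin(th) * yc + cos(th) * xc) / sc + (W + 1) / 2)
    apply_warp(src)
  }
  if (on_tf("elastic_transform")) {
    # cap the smoothing kernel so it fits small images
    sig <- min(cfg$elastic_sigma_px, (min(H, W) - 3) / 7)
    field <- function() {
      f <- matrix(runif(H * W, -1, 1), H, W)
      EBImage::gblur(f, sigma = sig) * cfg$elastic_alpha_px
    }
    g <- grid_rc()
    apply_warp(list(r = g$r + field(), c = g$c + field()))
  }
  if (on_tf("grid_distortion")) {
    distort_axis <- function(n, steps) {
      mult <- 1 + runif(steps, -1, 1) * cfg$grid_limit
      knots_dst <- seq(0, n, length.out = steps + 1)
      seg <- diff(knots_dst) * mult
      knots_src <- c(0, cumsum(seg)) * n / sum(seg)
      stats::approx(knots_dst, knots_src, xout = seq_len(n) - 0.5)$y + 0.5
    }
    rr <- distort_axis(H, cfg$grid_steps)
    cc <- distort_axis(W, cfg$grid_steps)
    apply_warp(list(r = matrix(rr, H, W), c = matrix(cc, H, W, byrow = TRUE)))
  }
  if (on_tf("optical_distortion")) {
    kdist <- runif(1, -1, 1) * cfg$optical_limit
    g <- grid_rc()
    yc <- (g$r - (H + 1) / 2) / (H / 2)
    xc <- (g$c - (W + 1) / 2) / (W / 2)
    r2 <- xc^2 + yc^2
    f <- 1 + kdist * r2
    apply_warp(list(r = yc * f * (H / 2) + (H + 1) / 2,
                    c = xc * f * (W / 2) + (W + 1) / 2))
  }
  if (on_tf("random_brightness_contrast")) {
    b <- runif(1, -1, 1) * cfg$brightness_limit
    ct <- 1 + runif(1, -1, 1) * cfg$contrast_limit
    image <- pmin(pmax((image - 0.5) * ct + 0.5 + b, 0), 1)
  }
  if (on_tf("invert")) {
    image <- 1 - image
  }
  list(image = image, mask = mask)
}
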