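#' Parameters of the synthetic chest phantom
#'
#' The phantom emulates the geometry that matters for cardiothoracic-ratio
#' (CTR) work on a posterior-anterior chest radiograph: two vertically
#' elongated elliptical lung fields whose outer borders define the internal
#' thoracic span, and a cardiac ellipse in the medial/inferior zone whose
#' horizontal extent defines the cardiac span. All geometry is expressed as
#' fractions of the image width/height, so the analytic cardiac and thoracic
#' widths (and hence the true CTR) are known exactly for every sample.
#'
#' Optional confounders mimic findings common in hemodialysis patients:
#' central venous catheters (a bright curve), pacemakers (a bright disc) and
#' pleural effusion (a shaded lower lateral lung zone). Artifacts alter pixel
#' intensities only; the label mask always encodes the anatomic truth.
#'
#' @param width_px,height_px image size in pixels.
#' @param lung_outer_left_frac,lung_outer_right_frac outermost thoracic
#'   columns as fractions of width; their difference is the thoracic span.
#' @param heart_center_frac,heart_halfwidth_frac cardiac ellipse centre and
#'   horizontal semi-axis as fractions of width; `2 * heart_halfwidth_frac`
#'   is the cardiac span.
#' @param heart_center_row_frac,heart_halfheight_frac cardiac ellipse centre
#'   row and vertical semi-axis as fractions of height.
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels on
#'   the `[0,1]` scale).
#' @param blur_sigma_px Gaussian blur applied to the rendered image, pixels.
#' @param artifact_flags character subset of
#'   `c("catheter", "pacemaker", "effusion")`.
#' @param jitter_sd per-sample Gaussian perturbation (truncated at 2.5 sd)
#'   applied to the geometric fractions before rasterization; the analytic
#'   truth is recomputed after jitter so raster and truth always agree.
#' @param effusion_hard_mode if `TRUE`, an effusion also truncates the lung
#'   label (hard cases where the boundary truth itself is eroded); off by
#'   default so the ground truth stays well defined.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(width_px = 256L, height_px = 256L,
                           lung_outer_left_frac = 0.10,
                           lung_outer_right_frac = 0.90,
                           heart_center_frac = 0.54,
                           heart_halfwidth_frac = 0.19,
                           heart_center_row_frac = 0.62,
                           heart_halfheight_frac = 0.16,
                           noise_sd = 0.04,
                           blur_sigma_px = 0.8,
                           artifact_flags = character(),
                           jitter_sd = 0.03,
                           effusion_hard_mode = FALSE) {
  check_count(width_px, "width_px", min = 16L)
  check_count(height_px, "height_px", min = 16L)
  for (nm in c("lung_outer_left_frac", "lung_outer_right_frac",
               "heart_center_frac", "heart_halfwidth_frac",
               "heart_center_row_frac", "heart_halfheight_frac")) {
    check_number(get(nm), nm, 0, 1, open_lower = TRUE, open_upper = TRUE)
  }
  check_number(noise_sd, "noise_sd", 0)
  check_number(blur_sigma_px, "blur_sigma_px", 0)
  check_number(jitter_sd, "jitter_sd", 0)
  if (lung_outer_right_frac <= lung_outer_left_frac) {
    stop_ctrseg("thoracic span must be positive (lung_outer_right_frac > lung_outer_left_frac)",
                "ctrseg_parameter_error")
  }
  if (heart_center_frac - heart_halfwidth_frac <= lung_outer_left_frac ||
      heart_center_frac + heart_halfwidth_frac >= lung_outer_right_frac) {
    stop_ctrseg("heart extent must lie inside the thoracic extent",
                "ctrseg_parameter_error")
  }
  bad <- setdiff(artifact_flags, c("catheter", "pacemaker", "effusion"))
  if (length(bad) > 0) {
    stop_ctrseg(paste0("unknown artifact flag(s): ", paste(bad, collapse = ", ")),
                "ctrseg_parameter_error")
  }
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    lung_outer_left_frac = lung_outer_left_frac,
    lung_outer_right_frac = lung_outer_right_frac,
    heart_center_frac = heart_center_frac,
    heart_halfwidth_frac = heart_halfwidth_frac,
    heart_center_row_frac = heart_center_row_frac,
    heart_halfheight_frac = heart_halfheight_frac,
    noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
    artifact_flags = artifact_flags, jitter_sd = jitter_sd,
    effusion_hard_mode = effusion_hard_mode
  ), class = "phantom_params")
}

# truncated N(0, sd) draws, clipped at 2.5 sd to keep geometry valid
jitter_draw <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  pmin(pmax(rnorm(n, 0, sd), -2.5 * sd), 2.5 * sd)
}

# In-ellipse indicator at pixel centres; (cx, cy) and semi-axes in continuous
# pixel units, pixel i (1-based) centred at i - 0.5.
ellipse_mask <- function(H, W, cx, cy, a, b) {
  xs <- (seq_len(W) - 0.5 - cx) / a
  ys <- (seq_len(H) - 0.5 - cy) / b
  outer(ys^2, xs^2, `+`) <= 1
}

#' Draw one synthetic chest phantom
#'
#' Deterministic for a fixed `(params, seed)` pair. Geometry fractions are
#' jittered first, truth (cardiac span, thoracic span, CTR) is recomputed from
#' the post-jitter fractions, and the label mask is rasterized from the same
#' fractions, so mask and analytic truth always agree to within pixel
#' discretization. Class precedence where ellipses overlap is
#' heart > lung > background, matching the disjoint silhouettes of a PA view
#' where the cardiac border occludes lung.
#'
#' @param params a [phantom_params()] object.
#' @param seed integer seed for jitter, noise and artifact placement.
#' @return an object of class `phantom_sample`: a list with `image`
#'   (numeric `height_px x width_px` matrix in `[0,1]`), `mask` (integer
#'   matrix with 0 = background, 1 = lung, 2 = heart),
#'   `true_cardiac_width_px`, `true_thoracic_width_px`, `true_ctr`, `seed`.
#' @export
#' @examples
#' p <- phantom_params(width_px = 96, height_px = 96, jitter_sd = 0)
#' s <- sample_phantom(p, seed = 1)
#' s$true_ctr
sample_phantom <- function(params, seed) {
  stopifnot(inherits(params, "phantom_params"))
  seed <- check_count(seed, "seed", min = 0L)
  with_seed(seed, sample_phantom_impl(params, seed))
}

sample_phantom_impl <- function(p, seed) {
  H <- p$height_px; W <- p$width_px
  j <- jitter_draw(8, p$jitter_sd)
  rl <- min(max(p$lung_outer_left_frac + j[1], 0.02), 0.45)
  ro <- max(min(p$lung_outer_right_frac + j[2], 0.98), rl + 0.2)
  cx <- p$heart_center_frac + j[3]
  hh <- max(p$heart_halfwidth_frac + j[4], 0.02)
  cy <- min(max(p$heart_center_row_frac + j[5], 0.2), 0.85)
  hb <- max(p$heart_halfheight_frac + j[6], 0.04)
  lung_cy <- min(max(0.48 + j[7], 0.3), 0.65)
  lung_b <- max(0.33 + j[8], 0.2)
  # keep the heart strictly inside the thoracic extent
  cx <- min(max(cx, rl + hh + 0.01), ro - hh - 0.01)
  if (cx - hh <= rl || cx + hh >= ro) {
    hh <- (ro - rl) / 2 - 0.02
    cx <- (rl + ro) / 2
  }

  # rasterize in continuous pixel units
  lungL <- ellipse_mask(H, W, cx = (rl + cx) / 2 * W, cy = lung_cy * H,
                        a = (cx - rl) / 2 * W, b = lung_b * H)
  lungR <- ellipse_mask(H, W, cx = (cx + ro) / 2 * W, cy = lung_cy * H,
                        a = (ro - cx) / 2 * W, b = lung_b * H)
  heart <- ellipse_mask(H, W, cx = cx * W, cy = cy * H, a = hh * W, b = hb * H)
  mask <- matrix(0L, H, W)
  mask[lungL | lungR] <- 1L
  mask[heart] <- 2L  # heart occludes lung

  # image: smooth background gradient + region shading
  img <- outer(0.35 + 0.15 * (seq_len(H) - 1) / (H - 1),
               1 + 0.05 * sin(pi * (seq_len(W) - 1) / (W - 1)))
  img[lungL | lungR] <- 0.15
  img[heart] <- 0.70
  img <- draw_artifacts(img, p, rl, ro, cx, lung_cy, lung_b, H, W)
  if (p$effusion_hard_mode && "effusion" %in% p$artifact_flags) {
    cut_row <- round((lung_cy + 0.8 * lung_b) * H)
    mask[seq(min(cut_row, H), H), ][mask[seq(min(cut_row, H), H), ] == 1L] <- 0L
  }
  if (p$blur_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = p$blur_sigma_px)
  }
  if (p$noise_sd > 0) {
    img <- img + matrix(rnorm(H * W, 0, p$noise_sd), H, W)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(
    image = img, mask = mask,
    true_cardiac_width_px = 2 * hh * W,
    true_thoracic_width_px = (ro - rl) * W,
    true_ctr = 2 * hh / (ro - rl),
    seed = seed,
    geometry = list(lung_outer_left_frac = rl, lung_outer_right_frac = ro,
                    heart_center_frac = cx, heart_halfwidth_frac = hh,
                    heart_center_row_frac = cy, heart_halfheight_frac = hb)
  ), class = "phantom_sample")
}

draw_artifacts <- function(img, p, rl, ro, cx, lung_cy, lung_b, H, W) {
  flags <- p$artifact_flags
  if ("catheter" %in% flags && runif(1) < 0.7) {
    # bright curve from the top midline into a lung field
    side <- sample(c(-1, 1), 1)
    t <- seq(0, 1, length.out = 4 * H)
    x0 <- cx * W; x1 <- (cx + side * (0.5 * (if (side > 0) ro - cx else cx - rl))) * W
    rr <- 1 + t * (lung_cy * H - 1)
    cc <- x0 + (x1 - x0) * t^1.7
    ij <- cbind(pmin(pmax(round(rr), 1), H), pmin(pmax(round(cc), 1), W))
    for (d in -1:1) {
      ij2 <- cbind(ij[, 1], pmin(pmax(ij[, 2] + d, 1), W))
      img[ij2] <- pmin(img[ij2] + 0.35, 1)
    }
  }
  if ("pacemaker" %in% flags && runif(1) < 0.7) {
    pcx <- (rl + 0.18 * (ro - rl) + runif(1, -0.02, 0.02)) * W
    pcy <- (lung_cy - 0.55 * lung_b + runif(1, -0.02, 0.02)) * H
    disc <- ellipse_mask(H, W, pcx, pcy, 0.045 * W, 0.04 * H)
    img[disc] <- 0.92
  }
  if ("effusion" %in% flags && runif(1) < 0.7) {
    side <- sample(c("left", "right"), 1)
    rows <- seq_len(H); cols <- seq_len(W)
    base_row <- (lung_cy + 0.3 * lung_b) * H
    fall <- pmin(pmax((rows - base_row) / (H - base_row), 0), 1)
    span <- if (side == "left") c(rl, cx) else c(cx, ro)
    colw <- as.numeric(cols - 0.5 >= span[1] * W & cols - 0.5 <= span[2] * W)
    img <- pmin(img + 0.25 * outer(fall, colw), 1)
  }
  img
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d  true CTR %.4f (cardiac %.1f px / thoracic %.1f px), seed %d\n",
              nrow(x$image), ncol(x$image), x$true_ctr,
              x$true_cardiac_width_px, x$true_thoracic_width_px, x$seed))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image PNGs, `n` mask PNGs and a CSV manifest with columns
#' `image_path,mask_path,true_ctr,seed`. Per-sample seeds are derived
#' deterministically from the master seed, so the whole dataset is
#' reproducible from `(params, seed)`.
#'
#' @param n number of samples.
#' @param params a [phantom_params()] object.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @return the manifest path (invisibly, the manifest tibble is attached as
#'   attribute `"manifest"`).
#' @export
generate_dataset <- function(n, params, seed, out_dir) {
  n <- check_count(n, "n")
  stopifnot(inherits(params, "phantom_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop_ctrseg(sprintf("output directory '%s' is not writable", out_dir),
                "ctrseg_io_error")
  }
  seeds <- derive_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_phantom(params, seeds[i])
    ipath <- file.path(out_dir, sprintf("img_%04d.png", i))
    mpath <- file.path(out_dir, sprintf("mask_%04d.png", i))
    write_image(s$image, ipath)
    write_mask(s$mask, mpath)
    rows[[i]] <- tibble::tibble(image_path = ipath, mask_path = mpath,
                                true_ctr = s$true_ctr, seed = seeds[i])
  }
  manifest <- dplyr::bind_rows(rows)
  mpath <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  structure(mpath, manifest = manifest)
}
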