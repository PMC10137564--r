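test_that("analytic CTR follows from the geometry fractions without jitter", {
  p <- phantom_params(width_px = 256, height_px = 256,
                      lung_outer_left_frac = 0.10, lung_outer_right_frac = 0.90,
                      heart_halfwidth_frac = 0.15, jitter_sd = 0)
  s <- sample_phantom(p, seed = 4)
  expect_equal(s$true_ctr, (2 * 0.15) / (0.90 - 0.10))
  expect_equal(s$true_cardiac_width_px, 2 * 0.15 * 256)
  expect_equal(s$true_thoracic_width_px, 0.8 * 256)
})

test_that("same params and seed give bit-identical samples", {
  p <- tiny_phantom_params(artifact_flags = c("catheter", "pacemaker", "effusion"))
  a <- sample_phantom(p, seed = 123)
  b <- sample_phantom(p, seed = 123)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$true_ctr, b$true_ctr)
  d <- sample_phantom(p, seed = 124)
  expect_false(identical(a$image, d$image))
})

test_that("mask raster brackets the analytic extents within one pixel", {
  p <- tiny_phantom_params()
  for (seed in 1:25) {
    s <- sample_phantom(p, seed)
    g <- s$geometry
    W <- ncol(s$mask)
    heart_cols <- range(which(colSums(s$mask == 2L) > 0))
    lung_cols <- range(which(colSums(s$mask == 1L) > 0))
    expect_lt(abs((heart_cols[1] - 1) - (g$heart_center_frac - g$heart_halfwidth_frac) * W), 1.5)
    expect_lt(abs(heart_cols[2] - (g$heart_center_frac + g$heart_halfwidth_frac) * W), 1.5)
    expect_lt(abs((lung_cols[1] - 1) - g$lung_outer_left_frac * W), 1.5)
    expect_lt(abs(lung_cols[2] - g$lung_outer_right_frac * W), 1.5)
    expect_true(sum(s$mask == 2L) >= 1 && sum(s$mask == 1L) >= 1)
  }
})

test_that("artifact overlays change pixel intensities but never the mask", {
  base <- tiny_phantom_params(noise_sd = 0, blur_sigma_px = 0)
  art <- tiny_phantom_params(noise_sd = 0, blur_sigma_px = 0,
                             artifact_flags = c("catheter", "pacemaker", "effusion"))
  found_change <- FALSE
  for (seed in 1:10) {
    a <- sample_phantom(base, seed)
    b <- sample_phantom(art, seed)
    expect_identical(a$mask, b$mask)
    if (!identical(a$image, b$image)) found_change <- TRUE
  }
  expect_true(found_change)
})

test_that("generate_dataset writes n consistent files and a reproducible manifest", {
  p <- tiny_phantom_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(10, p, seed = 99, out_dir = d1)
  m2 <- generate_dataset(10, p, seed = 99, out_dir = d2)
  t1 <- attr(m1, "manifest")
  t2 <- attr(m2, "manifest")
  expect_equal(nrow(t1), 10)
  expect_true(all(file.exists(t1$image_path)))
  expect_true(all(file.exists(t1$mask_path)))
  expect_equal(t1$true_ctr, t2$true_ctr)
  expect_equal(t1$seed, t2$seed)
  # files round-trip to the in-memory sample
  s <- sample_phantom(p, t1$seed[3])
  expect_identical(read_mask(t1$mask_path[3]), s$mask)
  expect_lt(max(abs(read_image(t1$image_path[3]) - s$image)), 1 / 255 + 1e-9)
})

test_that("cardiomegaly fraction matches the closed-form jitter distribution", {
  # ctr > 0.5 iff 2*hh' - 0.5*(ro' - rl') > 0 with independent (truncated)
  # Gaussian jitter on hh, ro, rl => closed-form normal probability
  p <- tiny_phantom_params()
  n <- 500
  man <- attr(generate_dataset(n, p, seed = 2024, out_dir = withr::local_tempdir()),
              "manifest")
  mu <- 2 * p$heart_halfwidth_frac -
    0.5 * (p$lung_outer_right_frac - p$lung_outer_left_frac)
  sd_lin <- sqrt(4 * p$jitter_sd^2 + 0.25 * 2 * p$jitter_sd^2)
  expected <- pnorm(mu / sd_lin)
  observed <- mean(man$true_ctr > 0.5)
  tol <- 3 * sqrt(expected * (1 - expected) / n) + 0.01  # binomial + truncation slack
  expect_lt(abs(observed - expected), tol)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(lung_outer_left_frac = 0), class = "ctrseg_parameter_error")
  expect_error(phantom_params(width_px = -5), class = "ctrseg_parameter_error")
  expect_error(phantom_params(lung_outer_left_frac = 0.9, lung_outer_right_frac = 0.1),
               class = "ctrseg_parameter_error")
  expect_error(phantom_params(heart_halfwidth_frac = 0.45, heart_center_frac = 0.5,
                              lung_outer_left_frac = 0.1, lung_outer_right_frac = 0.9),
               class = "ctrseg_parameter_error")
  expect_error(phantom_params(artifact_flags = "stethoscope"),
               class = "ctrseg_parameter_error")
})
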