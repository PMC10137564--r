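test_that("horizontal extent uses inclusive pixel counts", {
  m <- matrix(0L, 50, 100)
  m[20:30, 10:90] <- 1L
  m[22:28, 40:60] <- 2L
  expect_equal(unname(horizontal_extent(m, "heart")), c(40, 60, 21))
  expect_equal(unname(horizontal_extent(m, 1L)), c(10, 90, 81))
  single <- matrix(0L, 5, 5); single[3, 3] <- 2L; single[2, 2] <- 1L
  expect_equal(unname(horizontal_extent(single, "heart")["width_px"]), 1)
  expect_error(horizontal_extent(matrix(0L, 4, 4), "heart"),
               class = "ctrseg_missing_structure")
})

test_that("compute_ctr matches the column-scan oracle and the worked example", {
  m <- matrix(0L, 50, 100)
  m[20:30, 10:90] <- 1L
  m[22:28, 40:60] <- 2L
  r <- compute_ctr(m)
  expect_equal(r$ctr, 21 / 81)
  expect_equal(r$cardiac_width_px, 21)
  expect_equal(r$thoracic_width_px, 81)
  # heart extent equal to lung extent -> ctr 1
  m2 <- matrix(0L, 10, 10); m2[2:4, 3:8] <- 1L; m2[6:8, 3:8] <- 2L
  expect_equal(compute_ctr(m2)$ctr, 1.0)
  withr::with_seed(11, {
    for (rep in 1:60) {
      mk <- random_mask(sample(5:40, 1), sample(5:40, 1))
      got <- compute_ctr(mk, do_cleanup = FALSE)
      want <- oracle_ctr(mk)
      expect_identical(got$ctr, want$ctr)
      expect_identical(got$cardiac_width_px, as.numeric(want$cardiac))
      expect_identical(got$thoracic_width_px, as.numeric(want$thoracic))
    }
  })
})

test_that("phantom CTR recovers the analytic truth within discretization", {
  p <- tiny_phantom_params()
  for (seed in 1:40) {
    s <- sample_phantom(p, seed)
    r <- compute_ctr(s$mask)
    expect_lte(abs(r$ctr - s$true_ctr), 2 / ncol(s$mask))
  }
})

test_that("CTR is invariant to horizontal mirroring and covariant to scale", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      m <- random_mask(20, 30)
      r1 <- compute_ctr(m, do_cleanup = FALSE)$ctr
      r2 <- compute_ctr(m[, ncol(m):1], do_cleanup = FALSE)$ctr
      expect_identical(r1, r2)
    }
  })
  p <- tiny_phantom_params()
  s <- sample_phantom(p, 17)
  k <- 3L
  up <- resize_mask(s$mask, nrow(s$mask) * k, ncol(s$mask) * k)
  r0 <- compute_ctr(s$mask)
  r1 <- compute_ctr(up)
  expect_lt(abs(r1$cardiac_width_px / r0$cardiac_width_px - k), 0.15)
  expect_lt(abs(r1$thoracic_width_px / r0$thoracic_width_px - k), 0.15)
  expect_lte(abs(r1$ctr - r0$ctr), 2 / ncol(s$mask))
})

test_that("clean_mask keeps 2 lungs + 1 heart and matches the flood-fill oracle", {
  # speck removal
  m <- matrix(0L, 40, 40)
  m[5:25, 3:12] <- 1L; m[5:25, 25:36] <- 1L       # two lungs
  m[10:20, 15:22] <- 2L                            # heart
  m[35, 35] <- 2L                                  # 1-px heart speck
  m[30, 2] <- 1L                                   # 1-px lung speck
  cl <- clean_mask(m)
  expect_equal(cl[35, 35], 0L)
  expect_equal(cl[30, 2], 0L)
  expect_true(attr(cl, "cleanup_applied"))
  # intact 2-lung + 1-heart mask unchanged; idempotent
  m2 <- m; m2[35, 35] <- 0L; m2[30, 2] <- 0L
  cl2 <- clean_mask(m2)
  expect_identical(as.vector(cl2), as.vector(m2))
  expect_false(attr(cl2, "cleanup_applied"))
  cl3 <- clean_mask(cl)
  expect_identical(as.vector(cl3), as.vector(cl))
  # random multi-blob masks against the independent oracle
  withr::with_seed(21, {
    for (rep in 1:25) {
      mk <- random_mask(15, 15, p_bg = 0.7)
      got <- clean_mask(mk)
      want <- oracle_keep_largest(oracle_keep_largest(mk, 1L, 2L), 2L, 1L)
      expect_identical(as.vector(got), as.vector(want))
    }
  })
  expect_error(clean_mask(matrix(1L, 4, 4)), "heart",
               class = "ctrseg_missing_structure")
  expect_error(clean_mask(matrix(2L, 4, 4)), "lung",
               class = "ctrseg_missing_structure")
})

test_that("cardiomegaly calls use a strict 50% threshold", {
  expect_true(classify_cardiomegaly(0.534))
  expect_false(classify_cardiomegaly(0.50))
  expect_false(classify_cardiomegaly(0.499))
  expect_equal(classify_cardiomegaly(c(0.4, 0.6)), c(FALSE, TRUE))
  expect_error(classify_cardiomegaly(-0.1), class = "ctrseg_parameter_error")
})

test_that("ctr_table reports failures as human-review rows instead of aborting", {
  p <- tiny_phantom_params()
  s <- sample_phantom(p, 2)
  no_heart <- s$mask; no_heart[no_heart == 2L] <- 0L
  tab <- ctr_table(list(s$mask, no_heart))
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$ctr[1]))
  expect_true(is.na(tab$ctr[2]))
  expect_match(tab$error_note[2], "heart")
})
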