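test_that("gamma correction is exact on the hand-computed case and monotone", {
  img <- matrix(64L, 2, 2)
  expect_equal(gamma_correct(img, 0.5, max_value = 255),
               matrix(128L, 2, 2))
  # identity is bitwise
  set.seed(1)
  rnd <- matrix(sample.int(65535, 100), 10, 10)
  expect_identical(gamma_correct(rnd, 1), rnd)
  # pixel ordering preserved for any gamma
  v <- sort(sample.int(65535, 50))
  for (g in c(0.3, 0.7, 1.8)) {
    out <- gamma_correct(matrix(v, 1), g)
    expect_true(all(diff(as.vector(out)) >= 0))
  }
  expect_error(gamma_correct(rnd, 0), "gamma")
})

test_that("threshold calibration averages per-image percentiles", {
  one <- matrix(100L, 8, 8)
  expect_equal(calibrate_threshold(one, percentile = 50)$threshold, 100)
  expect_equal(calibrate_threshold(one, percentile = 99)$threshold, 100)
  two <- list(matrix(80L, 8, 8), matrix(120L, 8, 8))
  expect_equal(calibrate_threshold(two, percentile = 99)$threshold, 100)
  expect_error(calibrate_threshold(list()), "no control images")
})

test_that("calibration percentile matches the interpolation oracle", {
  set.seed(8)
  img <- matrix(sample.int(5000, 40 * 40, replace = TRUE), 40, 40)
  mask <- matrix(0L, 40, 40)
  mask[5:35, 5:35] <- 1L
  for (pct in c(50, 90, 99, 99.5)) {
    model <- calibrate_threshold(img, mask, percentile = pct)
    expect_equal(model$threshold,
                 percentile_oracle(as.numeric(img[mask > 0]), pct),
                 tolerance = 1e-12)
  }
})

test_that("a blank image yields no foci", {
  img <- matrix(0L, 32, 32)
  mask <- matrix(1L, 32, 32)
  expect_equal(nrow(detect_foci(img, mask, threshold = 10)), 0)
})

test_that("a single rendered disk is measured at its drawn diameter", {
  # rasterize a 0.3 um disk by hand at 0.1 um/px: pixel centres within the
  # 1.5 px radius of an off-grid centre
  img <- matrix(2000L, 64, 64)
  mask <- matrix(1L, 64, 64)
  centre <- c(32.3, 30.8)
  for (r in 28:37) for (cc in 26:35) {
    if ((r - centre[1])^2 + (cc - centre[2])^2 <= 1.5^2) img[r, cc] <- 20000L
  }
  f <- detect_foci(img, mask, threshold = 2000,
                   size_gate_um = c(0.1, 0.5), pixel_size_um = 0.1)
  expect_equal(nrow(f), 1)
  # within one pixel of quantization
  expect_lt(abs(f$diameter_um - 0.3), 0.1)
  expect_equal(f$cell, 1L)
  expect_lt(abs(f$centroid_row - centre[1]), 1)
})

test_that("component counts equal the flood-fill oracle on random images", {
  set.seed(9)
  for (i in 1:200) {
    nr <- sample(3:32, 1)
    nc <- sample(3:32, 1)
    dens <- runif(1, 0.05, 0.7)
    b <- matrix(runif(nr * nc) < dens, nr, nc)
    lab <- label_components(b)
    expect_equal(max(lab), flood_fill_count(b))
    # labelling is a partition of the foreground
    expect_equal(lab > 0, b)
  }
})

test_that("foci with centroids on background are discarded", {
  img <- matrix(0L, 20, 20)
  mask <- matrix(0L, 20, 20)
  mask[1:20, 1:9] <- 1L
  mask[1:20, 12:20] <- 2L
  # component centred in the mask gap (columns 10-11)
  img[10, 9:12] <- 100L
  f <- detect_foci(img, mask, threshold = 50, size_gate_um = c(0, 10),
                   pixel_size_um = 0.1)
  expect_equal(nrow(f), 0)
  # component centred inside cell 2 is kept
  img2 <- matrix(0L, 20, 20)
  img2[10, 13:15] <- 100L
  f2 <- detect_foci(img2, mask, threshold = 50, size_gate_um = c(0, 10),
                    pixel_size_um = 0.1)
  expect_equal(f2$cell, 2L)
})

test_that("focus counts are non-increasing in the threshold", {
  p <- image_sim_params(image_shape = c(128, 128), n_cells = 2,
                        foci_per_cell = 10, seed = 23)
  sim <- simulate_images(p)
  img <- sim$images[[1]]
  mask <- sim$masks[[1]]
  # between the noise ceiling and the focus plateau components only shrink
  # or vanish; above the plateau they fragment stochastically, so the
  # monotone regime is bounded by the focus intensity
  thresholds <- seq(3000, 18000, length.out = 21)
  counts <- vapply(thresholds, function(t) {
    nrow(detect_foci(img, mask, t, size_gate_um = c(0.1, 0.6),
                     pixel_size_um = p$pixel_size_um))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("detection is translation-equivariant", {
  p <- image_sim_params(image_shape = c(96, 96), n_cells = 1,
                        foci_per_cell = 6, seed = 24)
  sim <- simulate_images(p)
  img <- sim$images[[1]]
  mask <- sim$masks[[1]]
  thr <- calibrate_threshold(img, mask)$threshold
  shift <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, nrow(m) + dr, ncol(m) + dc)
    out[(dr + 1):(dr + nrow(m)), (dc + 1):(dc + ncol(m))] <- m
    out
  }
  f0 <- detect_foci(img, mask, thr, pixel_size_um = p$pixel_size_um)
  f1 <- detect_foci(shift(img, 7, 11), shift(mask, 7, 11), thr,
                    pixel_size_um = p$pixel_size_um)
  expect_equal(nrow(f1), nrow(f0))
  expect_equal(sort(f1$diameter_um), sort(f0$diameter_um))
  expect_equal(sort(f1$centroid_row), sort(f0$centroid_row + 7))
})

test_that("high-contrast detection recovers the exact truth count", {
  hits <- vapply(1:100, function(s) {
    p <- image_sim_params(image_shape = c(256, 256), pixel_size_um = 0.1,
                          n_cells = 1, foci_per_cell = 10,
                          focus_diameter_range_um = c(0.2, 0.4),
                          noise_sd = 0, seed = 1000 + s)
    sim <- simulate_images(p)
    thr <- calibrate_threshold(sim$images, sim$masks)
    f <- detect_foci(sim$images[[1]], sim$masks[[1]], thr$threshold,
                     size_gate_um = c(0.1, 0.5), pixel_size_um = 0.1)
    nrow(f) == nrow(sim$truth)
  }, TRUE)
  expect_equal(mean(hits), 1)
})

test_that("mean recall degrades monotonically with noise", {
  recall_at <- function(noise_sd) {
    r <- vapply(1:10, function(s) {
      p <- image_sim_params(image_shape = c(128, 128), pixel_size_um = 0.1,
                            n_cells = 1, foci_per_cell = 6,
                            focus_diameter_range_um = c(0.2, 0.4),
                            noise_sd = noise_sd, seed = 3000 + s)
      sim <- simulate_images(p)
      ctrl_p <- p
      ctrl_p$foci_per_cell <- 0
      ctrl_p$seed <- 4000L + s
      ctrl <- simulate_images(ctrl_p)
      thr <- calibrate_threshold(ctrl$images, ctrl$masks)
      f <- detect_foci(sim$images[[1]], sim$masks[[1]], thr$threshold,
                       size_gate_um = c(0.1, 0.5), pixel_size_um = 0.1)
      if (nrow(sim$truth) == 0) return(1)
      matched <- vapply(seq_len(nrow(sim$truth)), function(i) {
        any((f$centroid_row - sim$truth$row[i])^2 +
            (f$centroid_col - sim$truth$col[i])^2 <=
            (sim$truth$diameter_um[i] / 2 / 0.1 + 2)^2)
      }, TRUE)
      mean(matched)
    }, 0)
    mean(r)
  }
  recalls <- vapply(c(0, 3000, 8000, 15000), recall_at, 0)
  expect_true(all(diff(recalls) <= 1e-9))
  expect_equal(recalls[1], 1)
  expect_lt(recalls[4], recalls[1])
})

test_that("run_mbody calibrates per experiment and counts controls too", {
  p <- image_sim_params(image_shape = c(96, 96), n_cells = 2,
                        foci_per_cell = 4, seed = 25)
  a <- simulate_images(p, n_images = 2)
  p$seed <- 26L
  b <- simulate_images(p, n_images = 2)
  design <- tibble::tibble(image = 1:4, experiment = c("E1", "E1", "E2", "E2"),
                           condition = c("ctrl", "drug", "ctrl", "drug"),
                           is_control = c(TRUE, FALSE, TRUE, FALSE))
  res <- run_mbody(c(a$images[1], a$images[2], b$images[1], b$images[2]),
                   c(a$masks[1], a$masks[2], b$masks[1], b$masks[2]),
                   design, pixel_size_um = p$pixel_size_um)
  expect_equal(nrow(res$thresholds), 2)
  expect_setequal(unique(res$cells$condition), c("ctrl", "drug"))
  expect_equal(nrow(res$cells), 8)  # 2 cells x 4 images, zero rows included
  expect_error(run_mbody(a$images, a$masks,
                         tibble::tibble(image = 1:2, experiment = "E",
                                        condition = "x",
                                        is_control = FALSE)),
               "no control images")
})
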