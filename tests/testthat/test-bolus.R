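test_that("saturation-frame removal trims exactly the requested frames", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  trimmed <- discard_saturation_frames(ph$series, 3)
  expect_equal(dim(trimmed$signal)[1], 37)
  expect_equal(trimmed$signal[1, , , ], ph$series$signal[4, , , ])
  same <- discard_saturation_frames(ph$series, 0)
  expect_equal(same$signal, ph$series$signal)
  expect_error(discard_saturation_frames(ph$series, 35), "fewer than 8")
})

test_that("mean brain curve is the arithmetic voxel mean", {
  u <- array(100, dim = c(10, 2, 2, 2))
  ser <- dsc_series(u, te = 60, frame_spacing = 2,
                    brain_mask = array(TRUE, c(2, 2, 2)))
  expect_equal(mean_brain_curve(ser), rep(100, 10))

  two <- array(0, dim = c(10, 1, 1, 2))
  two[, , , 1] <- 80; two[, , , 2] <- 120
  ser2 <- dsc_series(two, te = 60, frame_spacing = 2,
                     brain_mask = array(TRUE, c(1, 1, 2)))
  expect_equal(mean_brain_curve(ser2), rep(100, 10))
  expect_error(mean_brain_curve(ser2, array(FALSE, c(1, 1, 2))), "empty")
})

test_that("mean brain curve matches the analytic class average", {
  sp <- phantom_spec(noise_sd = 0)
  ph <- generate_phantom(sp)
  lab <- ph$truth$labels
  tt <- ph$truth$frame_times
  g <- dscquant:::gamma_variate_unit(tt, sp$arrival, sp$shape, sp$scale)
  classes <- c("wm", "gm", "tumor")
  counts <- sapply(1:3, function(k) sum(lab == k))
  class_curves <- sapply(seq_along(classes), function(k)
    sp$baseline[[classes[k]]] * exp(-sp$te * sp$cbv[[classes[k]]] * g))
  analytic <- as.vector(class_curves %*% counts / sum(counts))
  expect_equal(mean_brain_curve(ph$series, lab > 0), analytic,
               tolerance = 1e-10)
})

test_that("a linear ramp yields no retained minima ridges", {
  ex <- cwt_extrema(seq(10, 100, length.out = 40))
  expect_length(ex$minima, 0)
})

test_that("wavelet ridges localize single and double dips", {
  x <- 100 - 40 * exp(-((1:40) - 20)^2 / (2 * 3^2))
  ex <- cwt_extrema(x)
  strength <- vapply(ex$minima, function(r) r$strength, 0)
  tip <- ex$minima[[which.max(strength)]]$tip
  expect_lte(abs(tip - 20), 1)

  x2 <- 100 - 40 * exp(-((1:40) - 12)^2 / 8) -
    40 * exp(-((1:40) - 28)^2 / 8)
  tips <- vapply(cwt_extrema(x2)$minima, function(r) r$tip, 0L)
  t1 <- tips[which.min(abs(tips - 12))]
  t2 <- tips[which.min(abs(tips - 28))]
  expect_lte(abs(t1 - 12), 1)
  expect_lte(abs(t2 - 28), 1)
  expect_gte(abs(t2 - t1), 10)
})

test_that("cwt_extrema validates its inputs", {
  expect_error(cwt_extrema(1:5), "at least 8")
  expect_error(cwt_extrema(rnorm(40), scales = c(2, 1)), "ascending")
  expect_error(cwt_extrema(rnorm(10), scales = 1:12), "support")
})

test_that("bolus location hits phantom truth within one frame", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  tm <- detect_bolus(discard_saturation_frames(ph$series, 3))
  expect_lte(abs(tm$entrance - ph$truth$entrance), 1)
  expect_lte(abs(tm$trough - ph$truth$trough), 1)
  expect_lte(abs(tm$exit - ph$truth$exit), 1)
  expect_true(tm$entrance < tm$trough && tm$trough < tm$exit)
  expect_equal(tm$baseline_window, c(1L, tm$entrance - 1L))
})

test_that("a monotone curve raises a no-bolus error", {
  x <- seq(100, 10, length.out = 40)
  expect_error(locate_bolus(cwt_extrema(x), x), "no bolus")
})

test_that("a symmetric dip gives equidistant entrance and exit", {
  x <- 100 - 50 * exp(-((1:41) - 21)^2 / (2 * 4^2))
  tm <- locate_bolus(cwt_extrema(x), x)
  expect_equal(tm$trough, 21)
  expect_equal(tm$trough - tm$entrance, tm$exit - tm$trough)
})

test_that("detection is invariant to positive scaling and offset", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- 300 - 150 * exp(-((1:40) - 18)^2 / (2 * 3^2)) + rnorm(40, 0, 4)
    tm <- locate_bolus(cwt_extrema(x), x)
    for (tr in list(c(3.7, 0), c(1, 250), c(0.02, 17))) {
      y <- tr[1] * x + tr[2]
      tm2 <- locate_bolus(cwt_extrema(y), y)
      expect_equal(tm2$entrance, tm$entrance)
      expect_equal(tm2$trough, tm$trough)
      expect_equal(tm2$exit, tm$exit)
    }
  }
})

test_that("per-voxel bounds: identity, shift, and noise fallback", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  ser <- discard_saturation_frames(ph$series, 3)
  tm <- detect_bolus(ser)
  conc <- to_concentration(ser, baseline_map(ser, tm), tm)
  C <- dscquant:::conc_matrix(conc)
  ref <- rowMeans(C[, as.vector(conc$mask)])
  n <- length(ref)

  expect_equal(unname(refine_voxel_bounds(ref, tm, ref)),
               c(tm$entrance, tm$exit))
  shifted <- c(ref[1], ref[1], ref[1:(n - 2)])
  expect_equal(unname(refine_voxel_bounds(shifted, tm, ref)),
               c(tm$entrance + 2L, tm$exit + 2L))
  expect_equal(unname(refine_voxel_bounds(rep(1, n), tm, ref)),
               c(tm$entrance, tm$exit))
  fallbacks <- vapply(1:40, function(s) {
    set.seed(s)
    all(refine_voxel_bounds(rnorm(n), tm, ref) ==
          c(tm$entrance, tm$exit))
  }, TRUE)
  expect_gte(mean(fallbacks), 0.95)
})

test_that("auto brain mask recovers the phantom head", {
  ph <- generate_phantom(phantom_spec(noise_sd = 10, seed = 5))
  ser <- ph$series; ser$brain_mask <- NULL
  m <- auto_brain_mask(ser)
  expect_gte(dice_coef(m, ph$truth$labels > 0), 0.98)
})
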