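test_that("reference curve is the non-enhancing mean with trapezoid cumulative", {
  n <- 20; dt <- 2.2
  curve <- sin(seq(0, 3, length.out = n)) + 1
  conc <- make_conc(matrix(curve, n, 5), frame_spacing = dt)
  mod <- build_reference_curve(conc, array(TRUE, dim = c(1, 1, 5)))
  expect_equal(mod$reference_curve, curve)

  const <- make_conc(matrix(2, n, 3), frame_spacing = dt)
  modc <- build_reference_curve(const, array(TRUE, dim = c(1, 1, 3)))
  expect_equal(modc$cumulative_reference[n], 2 * dt * (n - 1))

  expect_error(build_reference_curve(conc, array(FALSE, dim = c(1, 1, 5))),
               "empty")
})

test_that("cumulative trapezoid tracks the incomplete-gamma closed form", {
  dt <- 2; shape <- 3; scale <- 3; t0 <- 25
  tt <- (0:39) * dt
  g <- dscquant:::gamma_variate_unit(tt, t0, shape, scale)
  conc <- make_conc(matrix(g, length(g), 2), frame_spacing = dt)
  mod <- build_reference_curve(conc, array(TRUE, dim = c(1, 1, 2)))
  closed <- stats::pgamma(pmax(tt - t0, 0) / scale, shape + 1)
  total <- closed[length(closed)]
  expect_lt(max(abs(mod$cumulative_reference - closed)), 0.01 * total)
})

test_that("leakage fit recovers exact and generative coefficients", {
  dt <- 2.2
  tt <- (0:36) * dt
  ref <- 0.17 * dscquant:::gamma_variate_unit(tt, 18, 3, 3)
  cum <- as.vector(pracma::cumtrapz(tt, ref))
  tm <- bolus_timing(entrance = 9, trough = 13, exit = 23, n_frames = 37)

  # exact representation: voxel equals the reference
  conc <- make_conc(cbind(ref, ref), frame_spacing = dt)
  mod <- build_reference_curve(conc, array(TRUE, dim = c(1, 1, 2)))
  fit <- fit_leakage(conc, mod, tm)
  expect_equal(as.vector(fit$k1_map), c(1, 1), tolerance = 1e-12)
  expect_equal(as.vector(fit$k2_map), c(0, 0), tolerance = 1e-12)

  # seeded generative recovery: 0.8 * ref - 0.01 * cum + noise
  set.seed(31)
  nv <- 200
  Y <- matrix(0.8 * ref - 0.01 * cum, 37, nv) +
    matrix(rnorm(37 * nv, 0, 2e-4), 37, nv)
  # keep the reference clean: fit against the noiseless reference
  concY <- make_conc(cbind(ref, Y), frame_spacing = dt)
  ne <- array(c(TRUE, rep(FALSE, nv)), dim = c(1, 1, nv + 1))
  modY <- fit_leakage(concY, build_reference_curve(concY, ne), tm)
  k1 <- as.vector(modY$k1_map)[-1]; k2 <- as.vector(modY$k2_map)[-1]
  s1 <- as.vector(modY$k1_se)[-1];  s2 <- as.vector(modY$k2_se)[-1]
  expect_gte(mean(abs(k1 - 0.8) <= 3 * s1), 0.985)
  expect_gte(mean(abs(k2 - 0.01) <= 3 * s2), 0.985)

  # degenerate reference
  conc0 <- make_conc(matrix(0, 37, 2), frame_spacing = dt)
  mod0 <- build_reference_curve(conc0, array(TRUE, dim = c(1, 1, 2)))
  expect_error(fit_leakage(conc0, mod0, tm), "degenerate")
})

test_that("K2 = 0 leaves the corrected curves untouched", {
  dt <- 2.2
  tt <- (0:36) * dt
  ref <- 0.2 * dscquant:::gamma_variate_unit(tt, 18, 3, 3)
  tm <- bolus_timing(9, 13, 23, 37)
  conc <- make_conc(cbind(ref, 2 * ref, 0.5 * ref), frame_spacing = dt)
  mod <- fit_leakage(conc, build_reference_curve(
    conc, array(TRUE, dim = c(1, 1, 3))), tm)
  expect_equal(max(abs(as.vector(mod$k2_map))), 0, tolerance = 1e-12)
  corr <- correct_concentration(conc, mod)
  expect_equal(corr, dscquant:::conc_matrix(conc), tolerance = 1e-10)
})

test_that("trapezoidal integration reproduces the triangle area", {
  # triangle of height h over 2k frames between entrance and exit
  k <- 5L; h <- 0.02; dt <- 2.2
  n <- 20L
  curve <- rep(0, n)
  e <- 5L; x <- e + 2L * k
  curve[e:x] <- h * (1 - abs(seq(-k, k)) / k)
  tm <- bolus_timing(e, e + k, x, n)
  conc <- make_conc(matrix(curve, n, 1), frame_spacing = dt)
  maps <- integrate_cbv(conc, NULL, tm, per_voxel_bounds = FALSE)
  expect_equal(as.vector(maps$cbv_uncorrected), h * k * dt,
               tolerance = 1e-12)
  expect_equal(maps$cbv_corrected, maps$cbv_uncorrected)
})

test_that("CBV scales linearly with the concentration scale", {
  ph <- generate_phantom(phantom_spec(grid_dim = c(12L, 12L, 4L),
                                      noise_sd = 0))
  ser <- discard_saturation_frames(ph$series, 3)
  tm <- detect_bolus(ser)
  conc <- to_concentration(ser, baseline_map(ser, tm), tm)
  m1 <- integrate_cbv(conc, NULL, tm, per_voxel_bounds = FALSE)
  conc2 <- conc; conc2$delta_r2s <- conc$delta_r2s * 4
  m2 <- integrate_cbv(conc2, NULL, tm, per_voxel_bounds = FALSE)
  sel <- conc$mask
  expect_equal(m2$cbv_uncorrected[sel], 4 * m1$cbv_uncorrected[sel],
               tolerance = 1e-12)
})

test_that("widening bounds never shrinks the integral of a nonnegative curve", {
  dt <- 2.2; n <- 30L
  curve <- dscquant:::gamma_variate_unit((0:(n - 1)) * dt, 20, 3, 3)
  conc <- make_conc(matrix(curve, n, 1), frame_spacing = dt)
  vals <- sapply(0:5, function(pad) {
    tm <- bolus_timing(max(2L, 10L - pad), 15L, min(n, 22L + pad), n)
    as.vector(integrate_cbv(conc, NULL, tm,
                            per_voxel_bounds = FALSE)$cbv_uncorrected)
  })
  expect_true(all(diff(vals) >= -1e-15))
})

test_that("correction recovers truth better than no correction on leaky voxels", {
  dt <- 2.2
  tt <- (0:36) * dt
  ref <- 0.17 * dscquant:::gamma_variate_unit(tt, 18, 3, 3)
  cum <- as.vector(pracma::cumtrapz(tt, ref))
  tm <- bolus_timing(9, 13, 23, 37)
  set.seed(77)
  nv <- 200
  Y <- matrix(2 * ref - 0.008 * cum, 37, nv) +
    matrix(rnorm(37 * nv, 0, 2e-4), 37, nv)
  conc <- make_conc(cbind(ref, Y), frame_spacing = dt)
  ne <- array(c(TRUE, rep(FALSE, nv)), dim = c(1, 1, nv + 1))
  mod <- fit_leakage(conc, build_reference_curve(conc, ne), tm)
  maps <- integrate_cbv(conc, mod, tm, per_voxel_bounds = FALSE)
  w <- tm$entrance:tm$exit
  truth <- pracma::trapz(tt[w], 2 * ref[w])
  err_c <- abs(as.vector(maps$cbv_corrected)[-1] - truth)
  err_u <- abs(as.vector(maps$cbv_uncorrected)[-1] - truth)
  expect_gte(mean(err_c < err_u), 0.95)
})

test_that("phantom leakage: noiseless K1/K2 recovery is machine exact", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0, tumor_k2 = 0.01))
  fit <- dsc_quantify(ph$series, tumor_roi = ph$truth$labels == 3,
                      wm_prob = ph$truth$wm_prob)
  tum <- ph$truth$labels == 3
  expect_lt(max(abs(fit$maps$k1_map[tum] - ph$truth$k1[tum])), 1e-10)
  expect_lt(max(abs(fit$maps$k2_map[tum] - 0.01)), 1e-10)
})
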