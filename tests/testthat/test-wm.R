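test_that("feature curves truncate at the bolus entrance", {
  n <- 37L
  conc <- make_conc(matrix(rnorm(n * 12, 0.01, 0.001), n, 12))
  tm <- bolus_timing(11, 15, 25, n)
  fc <- feature_curves(conc, tm)
  expect_equal(ncol(fc$features), 27)          # frames 11..37
  expect_equal(nrow(fc$features), 12)

  # identical curves give identical features
  conc2 <- make_conc(matrix(rep(sin(1:n) + 2, 2), n, 2))
  fc2 <- feature_curves(conc2, tm)
  expect_equal(fc2$features[1, ], fc2$features[2, ])

  # non-finite voxels are dropped
  bad <- matrix(1, n, 3); bad[15, 2] <- NA       # inside the window
  conc3 <- make_conc(bad)
  conc3$mask[] <- TRUE
  fc3 <- feature_curves(conc3, tm)
  expect_equal(nrow(fc3$features), 2)
})

test_that("mean shift separates two well-separated blobs exactly", {
  set.seed(41)
  bw <- 1
  X <- rbind(matrix(rnorm(60 * 2, 0, 0.15), ncol = 2),
             sweep(matrix(rnorm(40 * 2, 0, 0.15), ncol = 2), 2,
                   c(10, 0), "+"))
  ms <- mean_shift_cluster(X, bandwidth = bw)
  expect_equal(length(ms$sizes), 2L)
  truth <- rep(1:2, c(60, 40))
  expect_true(same_partition(ms$labels, truth))
  # brute-force nearest-mode oracle
  D <- as.matrix(stats::dist(rbind(ms$modes, X)))[1:2, -(1:2)]
  expect_equal(ms$labels, unname(apply(D, 2, which.min)))
})

test_that("identical features collapse to a single cluster", {
  X <- matrix(1, 25, 3)
  ms <- mean_shift_cluster(X)
  expect_equal(length(ms$sizes), 1L)
  expect_true(all(ms$labels == 1L))
  expect_error(mean_shift_cluster(X[1:5, ]), "at least 10")
  expect_error(mean_shift_cluster(X, bandwidth = -1), "positive")
})

test_that("mode count is non-increasing in bandwidth", {
  set.seed(55)
  X <- rbind(matrix(rnorm(50, 0, 0.3), ncol = 1),
             matrix(rnorm(50, 4, 0.3), ncol = 1),
             matrix(rnorm(50, 9, 0.3), ncol = 1))
  ks <- sapply(c(0.5, 1.2, 3, 8, 20), function(bw)
    length(mean_shift_cluster(X, bandwidth = bw)$sizes))
  expect_true(all(diff(ks) <= 0))
  expect_equal(ks[length(ks)], 1L)
})

test_that("clustering is invariant to voxel enumeration order", {
  set.seed(66)
  X <- rbind(matrix(rnorm(80, 0, 0.4), ncol = 2),
             sweep(matrix(rnorm(60, 0, 0.4), ncol = 2), 2, c(6, 6), "+"))
  perm <- sample(nrow(X))
  a <- mean_shift_cluster(X, bandwidth = 2)
  b <- mean_shift_cluster(X[perm, ], bandwidth = 2)
  expect_true(same_partition(a$labels[perm], b$labels))
})

test_that("three-class phantom clusters into distinct tissue classes", {
  ph <- generate_phantom(phantom_spec(noise_sd = 10, seed = 12))
  ser <- discard_saturation_frames(ph$series, 3)
  tm <- detect_bolus(ser)
  conc <- to_concentration(ser, baseline_map(ser, tm), tm)
  cl <- cluster_tissue(conc, tm)
  expect_gte(length(cl$clustering$sizes), 3L)
  lab <- cl$label_map
  wm_true <- ph$truth$labels == 1
  purity <- sapply(seq_along(cl$clustering$sizes), function(k)
    mean(wm_true[lab == k]))
  expect_gte(max(purity), 0.8)
  # between-class feature distance exceeds within-class distance
  fc <- feature_curves(conc, tm)
  lab_v <- ph$truth$labels[fc$voxel_idx]
  mu <- sapply(1:3, function(k)
    colMeans(fc$features[lab_v == k, , drop = FALSE]))
  within <- mean(sqrt(rowSums(
    (fc$features[lab_v == 1, ] -
       matrix(mu[, 1], sum(lab_v == 1), ncol(fc$features),
              byrow = TRUE))^2)))
  between <- sqrt(sum((mu[, 1] - mu[, 3])^2))
  expect_gt(between, within)
})

test_that("WM cluster selection honors the probability gate", {
  lab <- array(1L, dim = c(2, 4, 4))
  prob1 <- array(1, dim = c(2, 4, 4))
  roi <- select_wm_cluster(lab, prob1)
  expect_equal(roi$n_voxels, 32L)
  expect_equal(roi$source, "automatic")

  prob09 <- array(0.90, dim = c(2, 4, 4))
  expect_error(select_wm_cluster(lab, prob09, threshold = 0.95),
               "0.95")
  # threshold is inclusive: exactly 0.95 passes
  prob95 <- array(0.95, dim = c(2, 4, 4))
  expect_equal(select_wm_cluster(lab, prob95)$n_voxels, 32L)
})

test_that("largest-count cluster wins and tumor voxels are excluded", {
  lab <- array(0L, dim = c(1, 1, 10))
  lab[1, 1, 1:6] <- 1L; lab[1, 1, 7:10] <- 2L
  prob <- array(0.99, dim = c(1, 1, 10))
  tum <- array(FALSE, dim = c(1, 1, 10)); tum[1, 1, 1] <- TRUE
  roi <- select_wm_cluster(lab, prob, tumor_mask = tum)
  expect_equal(roi$n_voxels, 5L)                 # cluster 1 minus tumor
  expect_false(any(roi$mask & tum))
})

test_that("manual WM ROI applies label lookup and exclusions", {
  lab <- array(0L, dim = c(2, 5, 5))
  lab[1, , ] <- 7L                                # 25 voxels labeled 7
  lab[2, 1, 1:5] <- 2L
  roi <- manual_wm_roi(lab, 7L)
  expect_equal(roi$n_voxels, 25L)
  expect_equal(roi$source, "manual")
  expect_error(manual_wm_roi(lab, 9L), "label")

  tum <- array(FALSE, dim = c(2, 5, 5)); tum[1, 1, ] <- TRUE
  roi2 <- manual_wm_roi(lab, 7L, tumor_mask = tum)
  expect_equal(roi2$n_voxels, 20L)
  expect_error(manual_wm_roi(lab, 7L, brain_mask = array(FALSE, c(2, 5, 5))),
               "empty")
})
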