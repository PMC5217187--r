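#' Per-voxel feature curves for tissue clustering
#'
#' Tissue classes are clustered on their concentration-time curves.
#' All frames before the bolus entrance are discarded (they are
#' baseline and carry no tissue contrast); voxels with any non-finite
#' value are excluded.
#'
#' @param conc a `dsc_concentration`.
#' @param timing a [bolus_timing()].
#' @param mask optional logical 3D mask; defaults to the concentration
#'   mask.
#' @return A list with `features` (voxels x frames matrix of
#'   \eqn{\Delta R_2^*} from the entrance frame on), `voxel_idx`
#'   (linear indices into the volume) and `frames` (retained frame
#'   indices).
#' @export
feature_curves <- function(conc, timing, mask = NULL) {
  if (is.null(mask)) mask <- conc$mask
  w <- timing$entrance:nrow(conc_matrix(conc))
  idx <- which(as.vector(mask) & as.vector(conc$mask))
  Fm <- t(conc_matrix(conc)[w, idx, drop = FALSE])
  ok <- rowSums(!is.finite(Fm)) == 0L
  list(features = Fm[ok, , drop = FALSE], voxel_idx = idx[ok], frames = w)
}

# Project the (centered, unscaled) curves onto the leading principal
# directions capturing `var_explained` of the variance. Full-length
# curves make bandwidth estimation unstable; a handful of components
# carries the class contrast. Per-frame standardization is deliberately
# NOT applied: it would inflate noise-only tail frames to unit variance
# and swamp the bolus-frame class separation.
reduce_features <- function(features, var_explained = 0.95) {
  p <- prcomp(features, center = TRUE, scale. = FALSE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- which(cum >= var_explained)[1L]
  if (is.na(k)) k <- ncol(p$x)
  p$x[, seq_len(max(k, 1L)), drop = FALSE]
}

#' Flat-kernel mean-shift clustering
#'
#' Nonparametric mode seeking: seeds placed on an axis-aligned grid of
#' cell size `bandwidth` (one seed per occupied cell, at the cell's
#' point mean) are iteratively moved to the mean of all points within
#' `bandwidth` until convergence. Converged modes closer than
#' `bandwidth / 2` are merged (the better-supported mode wins), and
#' every point is assigned to its nearest surviving mode. The procedure
#' involves no randomness and is invariant to point enumeration order
#' up to relabeling.
#'
#' When `bandwidth` is absent it is estimated as half the median
#' pairwise distance of an (at most) 500-point evenly spaced subsample.
#'
#' @param features numeric matrix, points in rows (>= 10 rows).
#' @param bandwidth positive kernel radius in feature-space distance,
#'   or `NULL` to estimate from the data.
#' @param max_iter,tol iteration cap and convergence tolerance
#'   (fraction of bandwidth).
#' @return An object of class `mean_shift`: integer `labels` (one per
#'   row, 1..K in decreasing cluster size), `modes` (K x d matrix),
#'   `bandwidth`, `sizes`.
#' @export
mean_shift_cluster <- function(features, bandwidth = NULL,
                               max_iter = 300L, tol = 1e-3) {
  X <- as.matrix(features)
  npt <- nrow(X)
  if (npt < 10L) stop("mean shift needs at least 10 points")
  if (is.null(bandwidth)) bandwidth <- estimate_bandwidth(X)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be positive")
  # grid seeding: one seed per occupied bandwidth-sized cell
  bins <- floor(sweep(X, 2L, rep(bandwidth, ncol(X)), "/"))
  key <- apply(bins, 1L, paste, collapse = ",")
  seeds <- do.call(rbind, lapply(split(seq_len(npt), key), function(i)
    colMeans(X[i, , drop = FALSE])))
  seeds <- seeds[order(rownames(seeds)), , drop = FALSE]  # deterministic order
  ptss <- rowSums(X^2)
  shift_once <- function(S) {
    D2 <- outer(rowSums(S^2), ptss, "+") - 2 * tcrossprod(S, X)
    inside <- D2 <= bandwidth^2
    cnt <- rowSums(inside)
    Snew <- (inside %*% X) / pmax(cnt, 1L)
    Snew[cnt == 0L, ] <- S[cnt == 0L, , drop = FALSE]
    list(S = Snew, count = cnt)
  }
  S <- seeds
  for (it in seq_len(max_iter)) {
    st <- shift_once(S)
    move <- sqrt(rowSums((st$S - S)^2))
    S <- st$S
    if (max(move) < tol * bandwidth) break
  }
  support <- shift_once(S)$count
  # merge modes within bandwidth/2, strongest support first
  ord <- order(-support, seq_along(support))
  kept <- integer()
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d <- sqrt(rowSums((S[kept, , drop = FALSE] -
                         matrix(S[i, ], length(kept), ncol(S),
                                byrow = TRUE))^2))
    if (all(d > bandwidth / 2)) kept <- c(kept, i)
  }
  modes <- S[kept, , drop = FALSE]
  D2 <- outer(rowSums(modes^2), ptss, "+") - 2 * tcrossprod(modes, X)
  labels <- apply(D2, 2L, which.min)
  # relabel by decreasing cluster size (ties: original order)
  sizes <- tabulate(labels, nbins = nrow(modes))
  newid <- order(-sizes, seq_along(sizes))
  relab <- integer(nrow(modes)); relab[newid] <- seq_along(newid)
  labels <- relab[labels]
  structure(list(labels = as.integer(labels),
                 modes = modes[newid, , drop = FALSE],
                 bandwidth = bandwidth,
                 sizes = sizes[newid]),
            class = "mean_shift")
}

#' @export
print.mean_shift <- function(x, ...) {
  cat("Mean-shift clustering: ", length(x$sizes), " mode(s), bandwidth ",
      signif(x$bandwidth, 4), "\n  cluster sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

estimate_bandwidth <- function(X, n_sub = 500L, factor = 0.5) {
  npt <- nrow(X)
  sub <- X[unique(round(seq(1L, npt, length.out = min(n_sub, npt)))), ,
           drop = FALSE]
  med <- median(dist(sub))
  if (!is.finite(med) || med <= 0)
    med <- .Machine$double.eps                  # all points identical
  factor * med
}

#' Cluster concentration curves of a series
#'
#' Convenience wrapper chaining [feature_curves()], frame-wise
#' z-scoring + PCA reduction (95% variance), and
#' [mean_shift_cluster()], returning a volumetric cluster result.
#'
#' @param conc a `dsc_concentration`.
#' @param timing a [bolus_timing()].
#' @param mask optional clustering mask.
#' @param bandwidth optional kernel bandwidth (estimated when `NULL`).
#' @param var_explained PCA variance fraction retained (default 0.95).
#' @return An object of class `tissue_clusters`: `label_map` (integer
#'   3D volume, 0 outside), `modes_curves` (per-cluster mean
#'   concentration curve over the retained frames), `clustering` (the
#'   `mean_shift` object), `voxel_idx`, `frames`.
#' @export
cluster_tissue <- function(conc, timing, mask = NULL, bandwidth = NULL,
                           var_explained = 0.95) {
  fc <- feature_curves(conc, timing, mask)
  Z <- reduce_features(fc$features, var_explained)
  ms <- mean_shift_cluster(Z, bandwidth)
  lab <- array(0L, dim = dim(conc$mask))
  lab[fc$voxel_idx] <- ms$labels
  K <- length(ms$sizes)
  modes_curves <- t(vapply(seq_len(K), function(k)
    colMeans(fc$features[ms$labels == k, , drop = FALSE]),
    numeric(ncol(fc$features))))
  structure(list(label_map = lab, modes_curves = modes_curves,
                 clustering = ms, voxel_idx = fc$voxel_idx,
                 frames = fc$frames),
            class = "tissue_clusters")
}

#' @export
print.tissue_clusters <- function(x, ...) {
  print(x$clustering)
  invisible(x)
}

new_wm_roi <- function(mask, source) {
  if (!any(mask)) stop("white-matter ROI is empty")
  structure(list(mask = mask, source = source, n_voxels = sum(mask)),
            class = "wm_roi")
}

#' @export
print.wm_roi <- function(x, ...) {
  cat("WM reference ROI (", x$source, "): ", x$n_voxels, " voxels\n",
      sep = "")
  invisible(x)
}

#' Select the white-matter cluster via a probability atlas
#'
#' Among voxels with WM probability at or above the threshold (default
#' 0.95, "at least 95%"), the cluster containing the largest count of
#' such voxels is taken as white matter (ties broken by higher mean
#' probability). The ROI is that cluster's voxels that also meet the
#' probability threshold and lie outside the tumor ROI.
#'
#' @param clusters a `tissue_clusters` result (or an integer 3D label
#'   map with 0 = unclustered).
#' @param wm_prob 3D WM probability map in `[0, 1]`, pre-aligned to the
#'   DSC grid.
#' @param threshold minimum WM probability, inclusive (default 0.95).
#' @param tumor_mask optional logical 3D tumor ROI to exclude.
#' @return A `wm_roi` (source `"automatic"`).
#' @export
select_wm_cluster <- function(clusters, wm_prob, threshold = 0.95,
                              tumor_mask = NULL) {
  lab <- if (inherits(clusters, "tissue_clusters")) clusters$label_map
         else clusters
  if (!identical(dim(lab), dim(wm_prob)))
    stop("probability map is not on the series grid")
  hi <- wm_prob >= threshold & lab > 0L
  if (!any(hi))
    stop("no clustered voxel reaches WM probability >= ", threshold)
  K <- max(lab)
  counts <- tabulate(lab[hi], nbins = K)
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    meanp <- vapply(best, function(k) mean(wm_prob[hi & lab == k]), 0)
    best <- best[which.max(meanp)]
  }
  roi <- hi & lab == best
  if (!is.null(tumor_mask)) roi <- roi & !tumor_mask
  if (!any(roi))
    stop("selected WM cluster is empty after thresholding/exclusions")
  new_wm_roi(roi, "automatic")
}

#' Manual white-matter ROI
#'
#' Builds the WM reference from a user-drawn label volume: voxels
#' carrying `label`, intersected with the brain mask and excluding the
#' tumor ROI.
#'
#' @param labels integer 3D label volume.
#' @param label the label value marking WM.
#' @param brain_mask optional logical 3D brain mask.
#' @param tumor_mask optional logical 3D tumor ROI.
#' @return A `wm_roi` (source `"manual"`).
#' @export
manual_wm_roi <- function(labels, label, brain_mask = NULL,
                          tumor_mask = NULL) {
  if (!any(labels == label))
    stop("label ", label, " not present in the ROI volume")
  roi <- labels == label
  if (!is.null(brain_mask)) roi <- roi & brain_mask
  if (!is.null(tumor_mask)) roi <- roi & !tumor_mask
  if (!any(roi)) stop("manual WM ROI is empty after exclusions")
  new_wm_roi(roi, "manual")
}
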