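#' Remove initial saturation frames
#'
#' The first frames of a gradient/spin-echo EPI perfusion series have not
#' reached steady state; by default the first 3 time points are dropped
#' before any further processing. All downstream frame indices refer to
#' the post-discard time axis.
#'
#' @param series a [dsc_series()].
#' @param n number of initial frames to remove (default 3).
#' @return A [dsc_series()] with `n` fewer frames and attribute
#'   `n_discarded` recording the removal.
#' @export
discard_saturation_frames <- function(series, n = 3L) {
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be non-negative")
  nt <- n_frames(series)
  if (nt - n < 8L)
    stop("removing ", n, " frames would leave fewer than 8 of ", nt)
  if (n == 0L) {
    attr(series, "n_discarded") <- 0L
    return(series)
  }
  out <- series
  out$signal <- series$signal[-seq_len(n), , , , drop = FALSE]
  attr(out, "n_discarded") <- n
  out
}

#' Derive a brain mask from the temporal mean
#'
#' When no brain mask accompanies the series, one is derived by Otsu
#' thresholding of the temporal-mean volume followed by keeping the
#' largest 6-connected component.
#'
#' @param series a [dsc_series()].
#' @return Logical 3D array `(z, y, x)`.
#' @export
auto_brain_mask <- function(series) {
  sp <- dim(series$signal)[2:4]
  tmean <- colMeans(as_frame_matrix(series$signal))
  dim(tmean) <- sp
  thr <- otsu_threshold(as.vector(tmean))
  largest_component(tmean >= thr)
}

brain_mask_of <- function(series) {
  m <- series$brain_mask
  if (is.null(m)) m <- auto_brain_mask(series)
  if (!any(m)) stop("brain mask is empty")
  m
}

#' Brain-average signal-time curve
#'
#' @param series a [dsc_series()].
#' @param mask optional logical 3D mask; defaults to the series' brain
#'   mask, derived by [auto_brain_mask()] when absent.
#' @return Numeric vector of length `n_frames`, the mean signal over mask
#'   voxels at each frame.
#' @export
mean_brain_curve <- function(series, mask = NULL) {
  if (is.null(mask)) mask <- brain_mask_of(series)
  if (!any(mask)) stop("brain mask is empty")
  rowMeans(as_frame_matrix(series$signal)[, as.vector(mask), drop = FALSE])
}

# Ricker (Mexican-hat) wavelet sampled on integer offsets, L2-normalized
# per scale; two vanishing moments, so constant and linear trends map to
# (near-)zero coefficients.
ricker_kernel <- function(scale) {
  hw <- ceiling(4 * scale)
  u <- seq(-hw, hw)
  (2 / (sqrt(3 * scale) * pi^0.25)) *
    (1 - (u / scale)^2) * exp(-u^2 / (2 * scale^2))
}

# Mirror padding that survives pad widths exceeding the curve length
# (reflection tiling).
pad_reflect <- function(x, hw) {
  n <- length(x)
  if (n < 2L) stop("cannot pad a curve of length < 2")
  period <- c(x, rev(x[-c(1L, n)]))                 # length 2n - 2
  idx <- ((seq(1L - hw, n + hw) - 1L) %% length(period)) + 1L
  period[idx]
}

cwt_ricker <- function(curve, scales) {
  n <- length(curve)
  W <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    k <- ricker_kernel(scales[j])
    hw <- (length(k) - 1L) %/% 2L
    xp <- pad_reflect(curve, hw)
    W[, j] <- vapply(seq_len(n),
                     function(i) sum(xp[i:(i + 2L * hw)] * k), 0)
  }
  W
}

# Strict-ish local extrema of one coefficient column, excluding a guard
# zone near the curve ends where padding dominates.
local_extrema_idx <- function(w, guard, minima, floor_mag) {
  n <- length(w)
  if (n < 3L) return(integer())
  s <- if (minima) -w else w
  i <- 2:(n - 1L)
  cand <- i[s[i] > s[i - 1L] & s[i] >= s[i + 1L]]
  cand <- cand[cand > guard & cand <= n - guard]
  cand[abs(w[cand]) > floor_mag]
}

#' Wavelet extrema and cross-scale ridges of a signal curve
#'
#' Performs a continuous wavelet transform of the curve with the Ricker
#' (Mexican-hat) wavelet over the given scales, locates the maxima and
#' minima of the coefficients at each scale, and links extrema of the
#' same polarity across adjacent scales into ridges. Only ridges
#' persisting over at least `min_ridge_length` scales are retained;
#' these identify the curve's genuine peak/dip features, with the
#' ridge's smallest-scale position giving the feature location.
#'
#' @param curve numeric signal-time curve, length >= 8.
#' @param scales positive ascending wavelet scales in frame units;
#'   default 1:12 spans first-pass bolus widths at ~2 s frame spacing.
#' @param min_ridge_length minimum number of linked scales for a ridge
#'   to be retained (default 3).
#' @param link_tol maximum position shift, in frames, allowed between
#'   extrema at adjacent scales within one ridge (default 2).
#' @return An object of class `wavelet_extrema`: lists of retained
#'   minima/maxima ridges (each with per-scale positions, scales,
#'   summed-|coefficient| strength, and the smallest-scale position
#'   `tip`), plus the coefficient matrix.
#' @export
cwt_extrema <- function(curve, scales = 1:12, min_ridge_length = 3L,
                        link_tol = 2L) {
  n <- length(curve)
  if (n < 8L) stop("curve must have at least 8 samples")
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be positive and strictly ascending")
  if (n < 2 * max(scales))
    stop("curve of length ", n, " is shorter than the support of scale ",
         max(scales))
  W <- cwt_ricker(curve, scales)
  floor_mag <- 1e-8 * diff(range(curve))
  ridges_for <- function(minima) {
    ext <- lapply(seq_along(scales), function(j)
      local_extrema_idx(W[, j], guard = ceiling(scales[j]), minima = minima,
                        floor_mag = floor_mag))
    claimed <- lapply(ext, function(e) logical(length(e)))
    ridges <- list()
    for (j0 in rev(seq_along(scales))) {        # seed at large scales first
      for (m in seq_along(ext[[j0]])) {
        if (claimed[[j0]][m]) next
        pos <- ext[[j0]][m]
        claimed[[j0]][m] <- TRUE
        chain_pos <- pos; chain_scale <- j0
        if (j0 > 1L) for (j in (j0 - 1L):1L) {
          cand <- which(!claimed[[j]] & abs(ext[[j]] - pos) <= link_tol)
          if (!length(cand)) break
          best <- cand[which.min(abs(ext[[j]][cand] - pos))]
          claimed[[j]][best] <- TRUE
          pos <- ext[[j]][best]
          chain_pos <- c(pos, chain_pos)
          chain_scale <- c(j, chain_scale)
        }
        if (length(chain_pos) >= min_ridge_length) {
          ridges[[length(ridges) + 1L]] <- list(
            positions = chain_pos,
            scales = scales[chain_scale],
            strength = sum(abs(W[cbind(chain_pos, chain_scale)])),
            tip = chain_pos[1L])
        }
      }
    }
    ridges
  }
  structure(list(minima = ridges_for(TRUE), maxima = ridges_for(FALSE),
                 scales = scales, coefficients = W, n = n),
            class = "wavelet_extrema")
}

#' @export
print.wavelet_extrema <- function(x, ...) {
  cat("Wavelet extrema over scales ", min(x$scales), "-", max(x$scales),
      ": ", length(x$minima), " minima ridge(s), ", length(x$maxima),
      " maxima ridge(s)\n", sep = "")
  for (r in x$minima)
    cat("  min ridge at frame ", r$tip, " (", length(r$positions),
        " scales, strength ", signif(r$strength, 4), ")\n", sep = "")
  invisible(x)
}

moving_average3 <- function(x) {
  n <- length(x)
  xp <- c(x[1L], x, x[n])
  (xp[1:n] + xp[2:(n + 1L)] + xp[3:(n + 2L)]) / 3
}

#' Bolus timing container
#'
#' @param entrance,trough,exit 1-based frame indices on the post-discard
#'   time axis, with `entrance < trough < exit`.
#' @param n_frames length of the (post-discard) series.
#' @param n_discarded how many initial frames were removed upstream.
#' @return An object of class `bolus_timing` with the baseline window
#'   `[1, entrance - 1]`.
#' @export
bolus_timing <- function(entrance, trough, exit, n_frames,
                         n_discarded = 0L) {
  entrance <- as.integer(entrance); trough <- as.integer(trough)
  exit <- as.integer(exit); n_frames <- as.integer(n_frames)
  if (!(entrance < trough && trough < exit))
    stop("bolus timing must satisfy entrance < trough < exit (got ",
         entrance, ", ", trough, ", ", exit, ")")
  if (entrance < 2L)
    stop("bolus entrance at the first frame leaves no baseline window")
  if (exit > n_frames) stop("bolus exit beyond the series length")
  structure(list(n_discarded = as.integer(n_discarded),
                 baseline_window = c(1L, entrance - 1L),
                 entrance = entrance, trough = trough, exit = exit,
                 n_frames = n_frames),
            class = "bolus_timing")
}

#' @export
print.bolus_timing <- function(x, ...) {
  cat("Bolus timing (post-discard frames, ", x$n_discarded,
      " discarded):\n", sep = "")
  cat("  baseline window [", x$baseline_window[1], ", ",
      x$baseline_window[2], "], entrance ", x$entrance, ", trough ",
      x$trough, ", exit ", x$exit, " of ", x$n_frames, " frames\n",
      sep = "")
  invisible(x)
}

#' Locate the bolus from wavelet ridges
#'
#' The bolus trough is the smallest-scale position of the strongest
#' retained minimum ridge (largest summed |coefficient|; ties broken by
#' the earlier position). Entrance and exit are the local maxima of the
#' 3-frame moving-average-smoothed curve nearest the trough on either
#' side; when the pre-bolus plateau or post-bolus recovery is monotone
#' and offers no strict maximum, the last/first frame within 5% of the
#' local extreme value (relative to the trough depth) is used instead,
#' i.e. the plateau end and the recovery point.
#'
#' @param extrema a [cwt_extrema()] result.
#' @param curve the signal-time curve the transform was computed on.
#' @param n_discarded recorded in the returned timing (default 0).
#' @return A [bolus_timing()].
#' @export
locate_bolus <- function(extrema, curve, n_discarded = 0L) {
  if (!inherits(extrema, "wavelet_extrema"))
    stop("`extrema` must come from cwt_extrema()")
  rid <- extrema$minima
  if (!length(rid))
    stop("no bolus detected: no persistent minimum ridge in the curve")
  strength <- vapply(rid, function(r) r$strength, 0)
  tips <- vapply(rid, function(r) r$tip, 0L)
  best <- which(strength == max(strength))
  best <- best[which.min(tips[best])]
  trough <- tips[best]
  n <- length(curve)
  if (trough <= 1L || trough >= n)
    stop("bolus trough at the series boundary (frame ", trough, ")")
  sm <- moving_average3(curve)
  strict_max <- function(i) sm[i] > sm[i - 1L] & sm[i] >= sm[i + 1L]
  # entrance: nearest smoothed local max before the trough, or plateau end
  pre <- 1:(trough - 1L)
  cand <- pre[pre >= 2L][strict_max(pre[pre >= 2L])]
  m_pre <- max(sm[pre]); depth_pre <- m_pre - sm[trough]
  if (depth_pre <= 0) stop("no bolus detected: trough is not below baseline")
  plateau <- max(pre[sm[pre] >= m_pre - 0.05 * depth_pre])
  entrance <- if (length(cand)) max(max(cand), plateau) else plateau
  # exit: nearest smoothed local max after the trough, or recovery point
  post <- (trough + 1L):n
  cand <- post[post <= n - 1L][strict_max(post[post <= n - 1L])]
  m_post <- max(sm[post]); depth_post <- m_post - sm[trough]
  if (depth_post <= 0) stop("no bolus detected: curve does not recover")
  recov <- min(post[sm[post] >= m_post - 0.05 * depth_post])
  exit <- if (length(cand)) min(min(cand), recov) else recov
  bolus_timing(entrance, trough, exit, n, n_discarded = n_discarded)
}

#' Detect bolus timing on a series
#'
#' Convenience wrapper: brain-average curve, wavelet transform, ridge
#' detection and bolus location in one call.
#'
#' @param series a [dsc_series()] (already saturation-trimmed).
#' @param mask optional brain mask.
#' @inheritParams cwt_extrema
#' @return A [bolus_timing()].
#' @export
detect_bolus <- function(series, mask = NULL, scales = 1:12,
                         min_ridge_length = 3L, link_tol = 2L) {
  curve <- mean_brain_curve(series, mask)
  ex <- cwt_extrema(curve, scales = scales,
                    min_ridge_length = min_ridge_length,
                    link_tol = link_tol)
  nd <- attr(series, "n_discarded")
  locate_bolus(ex, curve, n_discarded = if (is.null(nd)) 0L else nd)
}

#' Per-voxel integration bounds
#'
#' Refines the global bolus entrance/exit for one voxel's
#' concentration-time curve by finding the integer lag, within
#' `search_radius` frames, that maximizes the correlation between the
#' voxel curve and the reference (brain-mean) concentration curve over
#' the bolus window; the global bounds are shifted by that lag. Voxels
#' with no local structure (flat or weakly correlated, max correlation
#' < 0.3) fall back to the global bounds. Always returns valid bounds.
#'
#' @param voxel_curve one voxel's concentration-time curve.
#' @param timing the global [bolus_timing()].
#' @param reference the reference concentration curve (same length); the
#'   brain-mean concentration curve in pipeline use.
#' @param search_radius maximum lag in frames (default 3).
#' @return Integer vector `c(entrance, exit)`.
#' @export
refine_voxel_bounds <- function(voxel_curve, timing, reference,
                                search_radius = 3L) {
  lag <- best_bolus_lag(matrix(voxel_curve, ncol = 1L), timing, reference,
                        search_radius)
  c(entrance = timing$entrance + lag, exit = timing$exit + lag)
}

# Vectorized lag search: Y is frames x voxels. Returns one integer lag
# per voxel; 0 (the global bounds) for voxels without local structure:
# bolus-window peak below 3 baseline SDs above the baseline mean, or
# best correlation with the reference below 0.5.
best_bolus_lag <- function(Y, timing, reference, search_radius = 3L) {
  n <- nrow(Y)
  w <- timing$entrance:timing$exit
  lags <- seq(-as.integer(search_radius), as.integer(search_radius))
  lags <- lags[w[1] + lags >= 1L & w[length(w)] + lags <= n]
  r <- reference[w]
  rc <- r - mean(r)
  rn <- sqrt(sum(rc^2))
  cors <- matrix(NA_real_, length(lags), ncol(Y))
  for (i in seq_along(lags)) {
    Z <- Y[w + lags[i], , drop = FALSE]
    Zc <- sweep(Z, 2L, colMeans(Z))
    zn <- sqrt(colSums(Zc^2))
    cors[i, ] <- (crossprod(Zc, rc) / (zn * rn))[, 1L]
  }
  cors[!is.finite(cors)] <- -Inf
  # prefer smaller |lag| on ties: order candidate rows accordingly
  ord <- order(abs(lags), lags)
  best <- rep(0L, ncol(Y))
  bestv <- rep(-Inf, ncol(Y))
  for (i in ord) {
    better <- cors[i, ] > bestv + 1e-12
    best[better] <- lags[i]
    bestv[better] <- cors[i, better]
  }
  structured <- rep(TRUE, ncol(Y))
  bw <- timing$baseline_window[1]:timing$baseline_window[2]
  if (length(bw) >= 2L) {
    B <- Y[bw, , drop = FALSE]
    bsd <- sqrt(colSums(sweep(B, 2L, colMeans(B))^2) / (length(bw) - 1L))
    peak <- do.call(pmax, lapply(w, function(i) Y[i, ]))
    structured <- is.finite(bsd) & (peak - colMeans(B) > 3 * bsd)
  }
  best[bestv < 0.5 | !structured] <- 0L
  best
}
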