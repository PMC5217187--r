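#' Automatic non-enhancing tissue mask
#'
#' The leakage-correction reference curve must average over voxels whose
#' blood-brain barrier is intact. Starting from the concentration mask,
#' this removes (i) the tumor ROI when supplied and (ii) voxels whose
#' post-bolus tail fails to return to baseline: a voxel is flagged as
#' enhancing when the absolute mean \eqn{\Delta R_2^*} over the frames
#' after the bolus exit exceeds twice the voxel's baseline-window
#' standard deviation, floored at 5% of the voxel's bolus peak so the
#' residual first-pass tail of a noiseless curve does not count as
#' enhancement.
#'
#' @param conc a `dsc_concentration` (see [to_concentration()]).
#' @param timing a [bolus_timing()].
#' @param tumor_mask optional logical 3D tumor ROI to exclude.
#' @return Logical 3D array of non-enhancing voxels.
#' @export
nonenhancing_mask <- function(conc, timing, tumor_mask = NULL) {
  C <- conc_matrix(conc)
  n <- nrow(C)
  keep <- as.vector(conc$mask)
  if (!is.null(tumor_mask)) keep <- keep & !as.vector(tumor_mask)
  bw <- timing$baseline_window[1]:timing$baseline_window[2]
  tail_w <- seq(min(timing$exit + 1L, n), n)
  sd_base <- apply(C[bw, , drop = FALSE], 2L, sd)
  tail_mean <- colMeans(C[tail_w, , drop = FALSE])
  peak <- apply(C[timing$entrance:timing$exit, , drop = FALSE], 2L, max)
  thr <- pmax(2 * sd_base, 0.05 * abs(peak))
  enhancing <- is.finite(tail_mean) & is.finite(thr) &
    abs(tail_mean) > thr
  out <- keep & !enhancing
  dim(out) <- dim(conc$mask)
  out
}

#' Build the leakage-correction reference curve
#'
#' The reference curve \eqn{\bar{\Delta R_2^*}(t)} is the mean
#' concentration curve over non-enhancing voxels; its running
#' trapezoidal time-integral is precomputed for the linear leakage model
#' \deqn{\Delta R_2^{*,voxel}(t) \approx K_1\,\bar{\Delta R_2^*}(t)
#'   - K_2 \int_0^t \bar{\Delta R_2^*}(t')\,dt'.}
#'
#' @param conc a `dsc_concentration`.
#' @param nonenhancing logical 3D mask of non-enhancing voxels (see
#'   [nonenhancing_mask()]).
#' @return An object of class `leakage_model` with `reference_curve`,
#'   `cumulative_reference` (units 1/ms x s) and the frame spacing;
#'   K1/K2 maps are filled by [fit_leakage()].
#' @export
build_reference_curve <- function(conc, nonenhancing) {
  sel <- as.vector(nonenhancing) & as.vector(conc$mask)
  if (!any(sel)) stop("non-enhancing mask is empty")
  ref <- rowMeans(conc_matrix(conc)[, sel, drop = FALSE])
  tt <- (seq_along(ref) - 1) * conc$frame_spacing
  cum <- as.vector(pracma::cumtrapz(tt, ref))
  structure(list(reference_curve = ref, cumulative_reference = cum,
                 frame_spacing = conc$frame_spacing,
                 n_reference_voxels = sum(sel),
                 k1_map = NULL, k2_map = NULL),
            class = "leakage_model")
}

#' @export
print.leakage_model <- function(x, ...) {
  cat("Leakage model: reference over ", x$n_reference_voxels,
      " non-enhancing voxels, ", length(x$reference_curve), " frames\n",
      sep = "")
  if (!is.null(x$k1_map))
    cat("  fitted K1 median ", signif(median(x$k1_map[is.finite(x$k1_map)]), 3),
        ", K2 median ", signif(median(x$k2_map[is.finite(x$k2_map)]), 3),
        " (fit window ", x$fit_window[1], "-",
        x$fit_window[length(x$fit_window)], ")\n", sep = "")
  invisible(x)
}

#' Fit per-voxel leakage coefficients K1, K2
#'
#' Ordinary least squares of each voxel's concentration curve on the
#' two regressors of the reference-curve leakage model,
#' \eqn{[\bar{\Delta R_2^*}(t),\; -\int_0^t \bar{\Delta R_2^*}]},
#' over the frames from the bolus entrance to the end of the series
#' (the pre-bolus frames carry no leakage information). The corrected
#' curve is \eqn{measured(t) + K_2 \int_0^t \bar{\Delta R_2^*}}.
#' Coefficient standard errors from the OLS fit are stored alongside.
#'
#' @param conc a `dsc_concentration`.
#' @param model a `leakage_model` from [build_reference_curve()].
#' @param timing a [bolus_timing()].
#' @return The `leakage_model` with 3D `k1_map`, `k2_map`, `k1_se`,
#'   `k2_se` filled (NA outside the mask).
#' @export
fit_leakage <- function(conc, model, timing) {
  ref <- model$reference_curve
  cum <- model$cumulative_reference
  if (all(abs(ref) < .Machine$double.eps))
    stop("degenerate leakage fit: reference curve is identically zero")
  n <- length(ref)
  w <- timing$entrance:n
  X <- cbind(ref[w], -cum[w])
  XtXi <- solve(crossprod(X))
  sel <- as.vector(conc$mask)
  Y <- conc_matrix(conc)[w, sel, drop = FALSE]
  B <- XtXi %*% crossprod(X, Y)                       # 2 x nvox
  resid <- Y - X %*% B
  dfree <- length(w) - 2L
  s2 <- colSums(resid^2) / dfree
  sp <- dim(conc$mask)
  put <- function(v) { out <- array(NA_real_, sp); out[sel] <- v; out }
  model$k1_map <- put(B[1L, ])
  model$k2_map <- put(B[2L, ])
  model$k1_se <- put(sqrt(pmax(XtXi[1L, 1L] * s2, 0)))
  model$k2_se <- put(sqrt(pmax(XtXi[2L, 2L] * s2, 0)))
  model$fit_window <- w
  model
}

#' Leakage-corrected concentration curves
#'
#' @param conc a `dsc_concentration`.
#' @param model a fitted `leakage_model` (or `NULL` for no correction).
#' @return Matrix (frames x all voxels) of corrected curves; equal to the
#'   measured curves where no K2 is available.
#' @export
correct_concentration <- function(conc, model = NULL) {
  C <- conc_matrix(conc)
  if (is.null(model) || is.null(model$k2_map)) return(C)
  k2 <- as.vector(model$k2_map)
  add <- outer(model$cumulative_reference, ifelse(is.finite(k2), k2, 0))
  C + add
}

trapezoid_weights <- function(len, dt) {
  if (len == 1L) return(0)
  w <- rep(dt, len)
  w[c(1L, len)] <- dt / 2
  w
}

#' Trapezoidal CBV integration
#'
#' Integrates the (leakage-corrected) concentration curves between the
#' bolus entrance and exit with the trapezoidal rule at the acquired
#' frame spacing; no resampling or curve fitting is applied. With
#' `per_voxel_bounds = TRUE` the global bounds are shifted per voxel by
#' the best-correlation lag of that voxel's curve against the brain-mean
#' concentration curve (see [refine_voxel_bounds()]). Negative integrals
#' are retained. The uncorrected map is computed identically from the
#' measured curves.
#'
#' @param conc a `dsc_concentration`.
#' @param model a fitted `leakage_model`, or `NULL` to disable
#'   correction (corrected and uncorrected maps then coincide).
#' @param timing a [bolus_timing()].
#' @param per_voxel_bounds recalculate entrance/exit per voxel
#'   (default `TRUE`).
#' @param search_radius frames searched around the global bounds
#'   (default 3).
#' @return An object of class `cbv_maps`: `cbv_corrected`,
#'   `cbv_uncorrected`, `k1_map`, `k2_map`, `rcbv` (filled by
#'   [normalize_rcbv()]), `mask`, `grid`.
#' @export
integrate_cbv <- function(conc, model = NULL, timing,
                          per_voxel_bounds = TRUE, search_radius = 3L) {
  C <- conc_matrix(conc)
  Ccorr <- correct_concentration(conc, model)
  sel <- which(as.vector(conc$mask))
  dt <- conc$frame_spacing
  n <- nrow(C)
  lags <- rep(0L, length(sel))
  if (per_voxel_bounds && length(sel)) {
    refc <- rowMeans(C[, sel, drop = FALSE])
    lags <- best_bolus_lag(C[, sel, drop = FALSE], timing, refc,
                           search_radius)
  }
  sp <- dim(conc$mask)
  cbv_u <- array(NA_real_, sp)
  cbv_c <- array(NA_real_, sp)
  for (lag in unique(lags)) {
    idx <- sel[lags == lag]
    e <- max(1L, timing$entrance + lag)
    x <- min(n, timing$exit + lag)
    if (x <= e) { e <- timing$entrance; x <- timing$exit }
    w <- e:x
    tw <- trapezoid_weights(length(w), dt)
    cbv_u[idx] <- as.vector(crossprod(C[w, idx, drop = FALSE], tw))
    cbv_c[idx] <- as.vector(crossprod(Ccorr[w, idx, drop = FALSE], tw))
  }
  structure(list(cbv_uncorrected = cbv_u, cbv_corrected = cbv_c,
                 k1_map = if (!is.null(model)) model$k1_map,
                 k2_map = if (!is.null(model)) model$k2_map,
                 rcbv = NULL, wm_mean_cbv = NULL,
                 mask = conc$mask, grid = conc$grid,
                 per_voxel_bounds = per_voxel_bounds, timing = timing),
            class = "cbv_maps")
}

#' @export
print.cbv_maps <- function(x, ...) {
  v <- x$cbv_corrected[x$mask]
  cat("CBV maps over ", sum(x$mask), " voxels (per-voxel bounds: ",
      x$per_voxel_bounds, ")\n", sep = "")
  cat("  corrected CBV median ", signif(median(v, na.rm = TRUE), 3),
      if (!is.null(x$rcbv)) paste0("; rCBV filled (WM mean CBV ",
                                   signif(x$wm_mean_cbv, 3), ")"),
      "\n", sep = "")
  invisible(x)
}
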