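#' Per-voxel baseline signal map
#'
#' The baseline \eqn{S_{base}} is the per-voxel mean signal over the
#' pre-bolus baseline window (first frame through the frame before the
#' bolus entrance). A window of at least 3 frames is required for a
#' usable estimate.
#'
#' @param series a [dsc_series()] (post-discard).
#' @param timing a [bolus_timing()] on the same time axis.
#' @return 3D array `(z, y, x)` of baseline signal.
#' @export
baseline_map <- function(series, timing) {
  w <- timing$baseline_window[1]:timing$baseline_window[2]
  if (length(w) < 3L)
    stop("baseline window has ", length(w), " frames; at least 3 required")
  sp <- dim(series$signal)[2:4]
  sb <- colMeans(as_frame_matrix(series$signal)[w, , drop = FALSE])
  dim(sb) <- sp
  sb
}

#' Convert signal to \eqn{\Delta R_2^*} concentration curves
#'
#' Applies the standard DSC conversion
#' \deqn{\Delta R_2^*(t) = -\ln\big(S(t) / S_{base}\big) / TE}
#' per voxel and frame, with TE in milliseconds so \eqn{\Delta R_2^*} is
#' in 1/ms. The conversion is exactly invertible:
#' \eqn{S_{base} e^{-TE\,\Delta R_2^*(t)}} reproduces the signal to
#' machine precision. Negative values (T1-driven leakage overshoot when
#' \eqn{S(t) > S_{base}}) are retained; the leakage-correction model
#' depends on them. Voxels with non-positive signal at any frame cannot
#' be log-transformed and are excluded from the mask (flagged in
#' `excluded`).
#'
#' @param series a [dsc_series()] (post-discard).
#' @param s_base 3D baseline map from [baseline_map()].
#' @param timing optional [bolus_timing()] carried along for downstream
#'   stages.
#' @return An object of class `dsc_concentration`: `delta_r2s` (4D array
#'   `(t, z, y, x)`, 1/ms), `s_base`, `mask`, `excluded`, `te`,
#'   `frame_spacing`, `timing`, `grid`.
#' @export
to_concentration <- function(series, s_base, timing = NULL) {
  sp <- dim(series$signal)[2:4]
  if (!identical(dim(s_base), sp))
    stop("baseline map shape does not match the series")
  mask <- brain_mask_of(series)
  if (any(s_base[mask] <= 0, na.rm = TRUE))
    stop("non-positive baseline inside the brain mask; cannot convert")
  S <- as_frame_matrix(series$signal)
  nonpos <- colSums(S <= 0) > 0L
  excluded <- array(nonpos & as.vector(mask), dim = sp)
  mask <- mask & !excluded
  C <- -log(sweep(S, 2L, as.vector(s_base), "/")) / series$te
  C[, !as.vector(mask)] <- NA_real_
  dim(C) <- dim(series$signal)
  structure(list(delta_r2s = C, s_base = s_base, mask = mask,
                 excluded = excluded, te = series$te,
                 frame_spacing = series$frame_spacing, timing = timing,
                 grid = series$grid),
            class = "dsc_concentration")
}

#' @export
print.dsc_concentration <- function(x, ...) {
  d <- dim(x$delta_r2s)
  cat("Delta-R2* concentration series: ", d[1], " frames, ",
      sum(x$mask), " in-mask voxels (", sum(x$excluded),
      " excluded for non-positive signal)\n", sep = "")
  cat("  TE ", x$te, " ms; units 1/ms\n", sep = "")
  invisible(x)
}

#' Reconstruct signal from concentration
#'
#' Inverse of [to_concentration()]; used to verify that the conversion is
#' exactly invertible.
#'
#' @param conc a `dsc_concentration`.
#' @return 4D signal array `(t, z, y, x)` (NA outside the mask).
#' @export
concentration_to_signal <- function(conc) {
  S <- exp(-conc$te * as_frame_matrix(conc$delta_r2s))
  S <- sweep(S, 2L, as.vector(conc$s_base), "*")
  dim(S) <- dim(conc$delta_r2s)
  S
}

conc_matrix <- function(conc) as_frame_matrix(conc$delta_r2s)
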