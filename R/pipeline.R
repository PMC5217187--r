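#' Run the full DSC quantification pipeline
#'
#' End-to-end automated rCBV quantification on one DSC series:
#' saturation-frame removal, brain masking, wavelet bolus detection,
#' baseline and \eqn{\Delta R_2^*} conversion, leakage correction
#' against a non-enhancing reference, trapezoidal CBV integration with
#' per-voxel bounds, white-matter reference selection (automatic
#' mean-shift + probability-map gating, or a manual ROI), rCBV
#' normalization and ROI summaries. The run is fully deterministic:
#' identical inputs and configuration give bit-identical maps.
#'
#' @param series a [dsc_series()] (raw; saturation frames are removed
#'   here).
#' @param tumor_roi optional logical 3D tumor mask (or a `tumor_roi`).
#' @param wm_mode `"auto"` (mean-shift + probability gate; requires
#'   `wm_prob`) or `"manual"` (requires `wm_roi`).
#' @param wm_prob 3D WM probability map on the DSC grid (auto mode).
#' @param wm_roi logical 3D WM mask, or integer label volume used with
#'   `wm_label` (manual mode).
#' @param wm_label label selecting WM in a label `wm_roi` (default 1).
#' @param wm_threshold WM probability gate, inclusive (default 0.95).
#' @param leakage_correction apply the reference-curve leakage model
#'   (default `TRUE`).
#' @param per_voxel_bounds recalculate integration bounds per voxel
#'   (default `TRUE`).
#' @param saturation_frames initial frames to discard (default 3).
#' @param scales,min_ridge_length wavelet detection parameters (see
#'   [cwt_extrema()]).
#' @param search_radius per-voxel bound search radius in frames.
#' @param bandwidth optional mean-shift bandwidth (estimated when
#'   `NULL`).
#' @return An object of class `dsc_quant` with elements `timing`,
#'   `maps` (a `cbv_maps` with `rcbv` filled), `wm`, `tumor`,
#'   `clusters` (auto mode), `stats` (per-ROI data frame),
#'   `mean_curve`, `leakage` (the fitted `leakage_model` or `NULL`)
#'   and `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' fit <- dsc_quantify(ph$series, tumor_roi = ph$truth$labels == 3,
#'                     wm_prob = ph$truth$wm_prob)
#' fit
#' @export
dsc_quantify <- function(series, tumor_roi = NULL,
                         wm_mode = c("auto", "manual"),
                         wm_prob = NULL, wm_roi = NULL, wm_label = 1L,
                         wm_threshold = 0.95,
                         leakage_correction = TRUE,
                         per_voxel_bounds = TRUE,
                         saturation_frames = 3L, scales = 1:12,
                         min_ridge_length = 3L, search_radius = 3L,
                         bandwidth = NULL) {
  wm_mode <- match.arg(wm_mode)
  if (is.list(tumor_roi) && !is.null(tumor_roi$mask))
    tumor_roi <- tumor_roi$mask
  config <- list(wm_mode = wm_mode, wm_threshold = wm_threshold,
                 leakage_correction = leakage_correction,
                 per_voxel_bounds = per_voxel_bounds,
                 saturation_frames = as.integer(saturation_frames),
                 scales = scales, min_ridge_length = min_ridge_length,
                 search_radius = search_radius, bandwidth = bandwidth,
                 te = series$te, frame_spacing = series$frame_spacing)

  ser <- discard_saturation_frames(series, saturation_frames)
  if (is.null(ser$brain_mask)) ser$brain_mask <- auto_brain_mask(ser)
  curve <- mean_brain_curve(ser)
  ex <- cwt_extrema(curve, scales = scales,
                    min_ridge_length = min_ridge_length)
  timing <- locate_bolus(ex, curve,
                         n_discarded = attr(ser, "n_discarded"))

  sb <- baseline_map(ser, timing)
  conc <- to_concentration(ser, sb, timing)

  leak <- NULL
  if (leakage_correction) {
    ne <- nonenhancing_mask(conc, timing, tumor_mask = tumor_roi)
    leak <- build_reference_curve(conc, ne)
    leak <- fit_leakage(conc, leak, timing)
  }
  maps <- integrate_cbv(conc, leak, timing,
                        per_voxel_bounds = per_voxel_bounds,
                        search_radius = search_radius)

  clusters <- NULL
  if (wm_mode == "auto") {
    if (is.null(wm_prob))
      stop("automatic WM selection requires `wm_prob` (a WM ",
           "probability map on the DSC grid)")
    clusters <- cluster_tissue(conc, timing, bandwidth = bandwidth)
    wm <- select_wm_cluster(clusters, wm_prob,
                            threshold = wm_threshold,
                            tumor_mask = tumor_roi)
  } else {
    if (is.null(wm_roi))
      stop("manual WM selection requires `wm_roi`")
    if (is.logical(wm_roi))
      wm_roi <- array(as.integer(wm_roi), dim = dim(wm_roi))
    wm <- manual_wm_roi(wm_roi, wm_label, brain_mask = ser$brain_mask,
                        tumor_mask = tumor_roi)
  }

  maps <- normalize_rcbv(maps, wm)
  stats <- roi_stats(maps$rcbv, wm$mask, "wm")
  if (!is.null(tumor_roi) && any(tumor_roi))
    stats <- rbind(stats, roi_stats(maps$rcbv, tumor_roi, "tumor"))

  structure(list(timing = timing, maps = maps, wm = wm,
                 tumor = tumor_roi, clusters = clusters, stats = stats,
                 mean_curve = curve, leakage = leak, config = config),
            class = "dsc_quant")
}

#' @export
print.dsc_quant <- function(x, ...) {
  cat("DSC rCBV quantification\n")
  print(x$timing)
  cat("  leakage correction: ",
      if (is.null(x$leakage)) "off"
      else paste0("on (", x$leakage$n_reference_voxels,
                  " reference voxels)"), "\n", sep = "")
  cat("  WM reference: ", x$wm$source, ", ", x$wm$n_voxels,
      " voxels; mean WM CBV ", signif(x$maps$wm_mean_cbv, 4),
      "\n", sep = "")
  cat("  ROI statistics (rCBV):\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dsc_quant <- function(object, ...) {
  x <- object
  rc <- x$maps$rcbv[x$maps$mask]
  out <- list(timing = x$timing, stats = x$stats,
              rcbv_range = range(rc, finite = TRUE),
              wm_mean_cbv = x$maps$wm_mean_cbv,
              n_clusters = if (!is.null(x$clusters))
                length(x$clusters$clustering$sizes),
              config = x$config)
  class(out) <- "summary.dsc_quant"
  out
}

#' @export
print.summary.dsc_quant <- function(x, ...) {
  print(x$timing)
  cat("rCBV range in mask: [", signif(x$rcbv_range[1], 3), ", ",
      signif(x$rcbv_range[2], 3), "]\n", sep = "")
  if (!is.null(x$n_clusters))
    cat("tissue clusters found: ", x$n_clusters, "\n", sep = "")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dsc_quant <- function(x, slice = NULL, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  n <- length(x$mean_curve)
  plot(seq_len(n), x$mean_curve, type = "l", xlab = "frame",
       ylab = "mean brain signal", main = "bolus detection", ...)
  abline(v = c(x$timing$entrance, x$timing$trough, x$timing$exit),
         lty = c(2, 1, 2), col = c("blue", "red", "blue"))
  legend("bottomleft", legend = c("entrance/exit", "trough"),
         lty = c(2, 1), col = c("blue", "red"), bty = "n", cex = 0.8)
  r <- x$maps$rcbv
  if (is.null(slice)) slice <- ceiling(dim(r)[1] / 2)
  img <- t(r[slice, , ])                       # (y, x) -> x across
  img[!is.finite(img)] <- 0
  image(img, axes = FALSE, col = gray.colors(128),
        main = paste0("rCBV, slice z=", slice))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the parametric maps (CBV corrected/uncorrected, rCBV, K1, K2)
#' and the WM ROI as float32 NIfTI, the bolus timing and resolved
#' configuration as JSON, and the ROI statistics as CSV.
#'
#' @param fit a `dsc_quant` result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_quant_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- fit$maps$grid
  wv <- function(v, name) if (!is.null(v))
    write_map(v, file.path(dir, paste0(name, ".nii.gz")), g)
  wv(fit$maps$cbv_corrected, "cbv_corrected")
  wv(fit$maps$cbv_uncorrected, "cbv_uncorrected")
  wv(fit$maps$rcbv, "rcbv")
  wv(fit$maps$k1_map, "k1")
  wv(fit$maps$k2_map, "k2")
  wv(fit$wm$mask * 1.0, "wm_roi")
  timing <- fit$timing
  jsonlite::write_json(
    list(n_discarded = timing$n_discarded,
         baseline_window = timing$baseline_window,
         entrance = timing$entrance, trough = timing$trough,
         exit = timing$exit, n_frames = timing$n_frames,
         wm_source = fit$wm$source, wm_n_voxels = fit$wm$n_voxels,
         wm_mean_cbv = fit$maps$wm_mean_cbv,
         config = fit$config),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  write.csv(fit$stats, file.path(dir, "roi_stats.csv"),
            row.names = FALSE)
  invisible(dir)
}
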