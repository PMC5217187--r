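#' Normalize CBV to the white-matter reference (rCBV)
#'
#' Divides the corrected CBV map by the mean corrected CBV over the
#' normal-appearing white-matter ROI. By construction the mean rCBV
#' over the WM ROI is exactly 1.
#'
#' @param cbv a `cbv_maps` object from [integrate_cbv()].
#' @param wm a `wm_roi`.
#' @return The `cbv_maps` object with `rcbv` and `wm_mean_cbv` filled.
#' @export
normalize_rcbv <- function(cbv, wm) {
  sel <- wm$mask & is.finite(cbv$cbv_corrected)
  if (!any(sel)) stop("WM ROI contains no finite CBV voxel")
  m <- mean(cbv$cbv_corrected[sel])
  if (!is.finite(m) || m <= 0)
    stop("non-positive mean WM CBV (", signif(m, 4),
         "); cannot normalize")
  cbv$rcbv <- cbv$cbv_corrected / m
  cbv$wm_mean_cbv <- m
  cbv
}

#' ROI summary statistics
#'
#' The two first-order summaries reported per ROI: the mean and the
#' 95th percentile of rCBV over finite ROI voxels. The percentile uses
#' linear interpolation between closest ranks (R quantile type 7); the
#' rule is recorded in the result. Negative rCBV voxels are included
#' (no undocumented filtering).
#'
#' @param map 3D map (typically rCBV).
#' @param roi logical 3D mask (or a `wm_roi`/`tumor_roi`).
#' @param name ROI name for reporting.
#' @return A one-row `data.frame` with `roi`, `n_voxels`, `mean`,
#'   `p95`, and attribute `percentile_method`.
#' @export
roi_stats <- function(map, roi, name = "roi") {
  if (is.list(roi) && !is.null(roi$mask)) roi <- roi$mask
  v <- map[roi]
  v <- v[is.finite(v)]
  if (!length(v)) stop("ROI '", name, "' has no finite voxels")
  out <- data.frame(roi = name, n_voxels = length(v), mean = mean(v),
                    p95 = unname(quantile(v, 0.95, type = 7)),
                    stringsAsFactors = FALSE)
  attr(out, "percentile_method") <- "linear interpolation (R type 7)"
  out
}

#' Bland-Altman agreement analysis
#'
#' Paired differences `d = a - b`: bias is `mean(d)` and the limits of
#' agreement are `bias +/- 2 * sd(d)` with the sample (n-1) standard
#' deviation, matching the 2*SD convention of the comparison plots.
#'
#' @param a,b paired measurement vectors of equal length >= 2.
#' @return An object of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n_pairs`, `means`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs required")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 2 * s,
                 loa_high = bias + 2 * s, sd_diff = s,
                 n_pairs = length(d), means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n_pairs, ")\n", sep = "")
  cat("  bias ", signif(x$bias, 4), ", limits of agreement [",
      signif(x$loa_low, 4), ", ", signif(x$loa_high, 4),
      "] (bias +/- 2 SD)\n", sep = "")
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of pair",
                              ylab = "difference", ...) {
  plot(x$means, x$diffs, xlab = xlab, ylab = ylab, pch = 19, ...)
  abline(h = x$bias)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' One-way random-effects intraclass correlation
#'
#' ICC from the one-way random-effects model: with between-subject and
#' within-subject mean squares \eqn{MS_B} and \eqn{MS_W} from the
#' one-way ANOVA of an `n` subjects x `k` raters table,
#' \deqn{ICC(1,1) = \frac{MS_B - MS_W}{MS_B + (k - 1) MS_W}}
#' (single-measure form, the default) or
#' \eqn{ICC(1,k) = (MS_B - MS_W)/MS_B} (average-measure form).
#'
#' @param ratings complete numeric matrix or data frame, subjects in
#'   rows, raters in columns (`n >= 2`, `k >= 2`, no missing cells).
#' @param type `"single"` for ICC(1,1) (default) or `"average"` for
#'   ICC(1,k).
#' @return An object of class `icc`: `icc`, `type`, `msb`, `msw`,
#'   `n`, `k`.
#' @export
icc_oneway <- function(ratings, type = c("single", "average")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(x)))
    stop("ratings table has missing or non-finite cells")
  rowm <- rowMeans(x)
  grand <- mean(x)
  msb <- k * sum((rowm - grand)^2) / (n - 1L)
  msw <- sum((x - rowm)^2) / (n * (k - 1L))
  if (msb <= .Machine$double.eps * grand^2 && msw == 0)
    stop("degenerate ratings: zero total variance, ICC undefined")
  icc <- if (type == "single") (msb - msw) / (msb + (k - 1L) * msw)
         else (msb - msw) / msb
  structure(list(icc = icc, type = type, msb = msb, msw = msw,
                 n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat("One-way random-effects ICC (", x$type, " measure): ",
      signif(x$icc, 4), "  [n = ", x$n, ", k = ", x$k, "]\n", sep = "")
  invisible(x)
}
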