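#' Otsu threshold of an intensity sample
#'
#' Classic Otsu thresholding: the intensity range is divided into
#' `n_bins` equal-width bins and the inter-bin cut maximizing the
#' between-class variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} is
#' chosen (ties resolved toward the lowest cut). The returned threshold
#' is the upper edge of the chosen bin, so `x >= threshold` selects the
#' bright class. Because bins are placed relative to the sample range,
#' the induced partition is invariant under affine intensity rescaling.
#'
#' @param x numeric vector of intensities (finite values used).
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities")
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate histogram: all intensities are equal")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  p <- h / sum(h)
  w0 <- cumsum(p)                     # class 0 = bins 1..k
  mu <- cumsum(p * mids)
  muT <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (muT * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  kstar <- which.max(bcv)             # first maximum: lowest cut
  breaks[kstar + 1L]
}

#' Finalize a tumor ROI by Otsu thresholding within a boundary
#'
#' A user-supplied generous boundary around the enhancing tumor is
#' refined on the post-contrast T1-weighted image: the Otsu threshold
#' of the intensities inside the boundary separates enhancing from
#' non-enhancing tissue, and the largest 6-connected bright component
#' is kept as the tumor ROI. The T1w image must already be on the DSC
#' grid.
#'
#' @param t1_post 3D post-contrast T1w intensity volume `(z, y, x)`.
#' @param boundary logical or label 3D volume marking the generous
#'   boundary (non-zero = inside).
#' @param n_bins histogram bins for the Otsu threshold (default 256).
#' @return An object of class `tumor_roi`: logical `mask` and
#'   `threshold_used`.
#' @export
otsu_within_boundary <- function(t1_post, boundary, n_bins = 256L) {
  b <- boundary != 0
  if (!any(b)) stop("tumor boundary is empty")
  vals <- t1_post[b]
  if (length(unique(vals[is.finite(vals)])) < 2L)
    stop("degenerate histogram: boundary intensities are constant")
  thr <- otsu_threshold(vals, n_bins)
  mask <- b & t1_post >= thr
  if (!any(mask)) stop("no voxel above the Otsu threshold")
  structure(list(mask = largest_component(mask), threshold_used = thr),
            class = "tumor_roi")
}

#' @export
print.tumor_roi <- function(x, ...) {
  cat("Tumor ROI: ", sum(x$mask), " voxels (Otsu threshold ",
      signif(x$threshold_used, 5), ")\n", sep = "")
  invisible(x)
}

#' Largest 6-connected component of a 3D mask
#'
#' Face-connectivity flood fill; used to clean the auto brain mask and
#' the thresholded tumor ROI.
#'
#' @param mask logical 3D array.
#' @return Logical 3D array keeping only the largest component (all
#'   `FALSE` if the input has no `TRUE` voxel).
#' @export
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(array(FALSE, d))
  strides <- c(1L, d[1], d[1] * d[2])
  coords <- arrayInd(idx, d)
  nvox <- prod(d)
  cur <- 0L
  best_lab <- 0L; best_n <- 0L
  queue <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s; qn <- 1L; comp_n <- 0L
    while (qn > 0L) {
      v <- queue[qn]; qn <- qn - 1L
      comp_n <- comp_n + 1L
      ci <- arrayInd(v, d)
      for (ax in 1:3) for (dir in c(-1L, 1L)) {
        if (ci[ax] + dir < 1L || ci[ax] + dir > d[ax]) next
        nb <- v + dir * strides[ax]
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- nb
        }
      }
    }
    if (comp_n > best_n) { best_n <- comp_n; best_lab <- cur }
  }
  lab == best_lab
}
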