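# Shared fixtures: everything is generated in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Minimal concentration object from a frames-by-voxels curve matrix,
# for exercising the leakage/integration stages in isolation.
make_conc <- function(curves, frame_spacing = 2.2, te = 60) {
  curves <- as.matrix(curves)
  nt <- nrow(curves); nv <- ncol(curves)
  arr <- array(curves, dim = c(nt, 1L, 1L, nv))
  structure(list(delta_r2s = arr,
                 s_base = array(300, dim = c(1L, 1L, nv)),
                 mask = array(TRUE, dim = c(1L, 1L, nv)),
                 excluded = array(FALSE, dim = c(1L, 1L, nv)),
                 te = te, frame_spacing = frame_spacing,
                 timing = NULL, grid = dsc_grid(c(nv, 1L, 1L))),
            class = "dsc_concentration")
}

# Two partitions are equal up to label renaming.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

# Independent brute-force Otsu: exhaustive search of the between-class
# variance over all bin cuts, computed from first principles.
otsu_bruteforce <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(h[1:k]); n1 <- sum(h) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(h[1:k] * mids[1:k]) / n0
    mu1 <- sum(h[(k + 1L):n_bins] * mids[(k + 1L):n_bins]) / n1
    v <- (n0 / sum(h)) * (n1 / sum(h)) * (mu0 - mu1)^2
    if (v > best_v + 1e-15) { best_v <- v; best_k <- k }
  }
  breaks[best_k + 1L]
}

# ICC(1,1) via stats::aov mean squares (independent route).
icc1_via_aov <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), times = k)))
  ms <- summary(stats::aov(y ~ subj, data = d))[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}
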