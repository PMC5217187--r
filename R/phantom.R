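#' Synthetic DSC phantom specification
#'
#' Defines the acquisition and tissue parameters of the seeded 4D DSC
#' phantom. Defaults emulate the target acquisition: 40 frames at 2.2 s
#' spacing (TR ~2.2 s), TE 60 ms, bolus appearing in the brain 25 s
#' after acquisition start, with a gamma-variate first pass
#' \eqn{c(t) \propto (t - t_0)^{\alpha} e^{-(t - t_0)/\beta}} shared by
#' all tissue classes and scaled per class so that its analytic time
#' integral equals the class CBV (WM : GM : tumor = 1 : 2 : 3 by
#' default). Optional tumor leakage is generated in concentration space
#' with the same linear reference-curve model the correction fits, so
#' coefficient recovery has an exact oracle. Gaussian noise is added to
#' the signal.
#'
#' @param grid_dim spatial dimensions (x, y, z); default `c(32, 32, 8)`.
#' @param n_frames number of time frames (default 40).
#' @param frame_spacing seconds per frame (default 2.2).
#' @param te echo time in ms (default 60).
#' @param arrival bolus arrival time in seconds from acquisition start
#'   (default 25).
#' @param shape,scale gamma-variate exponent \eqn{\alpha} (default 3)
#'   and time constant \eqn{\beta} in seconds (default 3); first-pass
#'   peak at \eqn{t_0 + \alpha\beta}.
#' @param baseline named baseline signal per class
#'   (`background`, `wm`, `gm`, `tumor`).
#' @param cbv named true CBV per class (units: 1/ms x s); defaults give
#'   peak \eqn{\Delta R_2^*} of ~0.010 (WM) to ~0.029 (tumor) 1/ms,
#'   i.e. 45-80% peak signal drops at TE 60 ms.
#' @param tumor_k2 leakage coefficient K2 of tumor voxels relative to
#'   the non-enhancing reference curve (default 0 = no leakage).
#' @param noise_sd Gaussian signal noise SD (default 10, i.e. baseline
#'   SNR 30 for WM); 0 for noiseless phantoms.
#' @param seed integer seed fixing every random draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(32L, 32L, 8L), n_frames = 40L,
                         frame_spacing = 2.2, te = 60, arrival = 25,
                         shape = 3, scale = 3,
                         baseline = c(background = 5, wm = 300,
                                      gm = 340, tumor = 320),
                         cbv = c(wm = 0.13, gm = 0.26, tumor = 0.39),
                         tumor_k2 = 0, noise_sd = 10, seed = 1L) {
  if (arrival >= (n_frames - 1) * frame_spacing)
    stop("bolus arrival lies beyond the series duration")
  if (shape <= 0 || scale <= 0 || frame_spacing <= 0 || te <= 0)
    stop("all rates must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(grid_dim = as.integer(grid_dim),
                 n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, te = te,
                 arrival = arrival, shape = shape, scale = scale,
                 baseline = baseline, cbv = cbv, tumor_k2 = tumor_k2,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# unit-integral gamma-variate first pass evaluated at times tt (s)
gamma_variate_unit <- function(tt, arrival, shape, scale) {
  u <- pmax(tt - arrival, 0)
  g <- ifelse(u > 0, u^shape * exp(-u / scale), 0)
  g / (gamma(shape + 1) * scale^(shape + 1))
}

# class label volume in internal (z, y, x) order:
# 0 background, 1 WM, 2 GM (2-voxel rim of the brain block in x/y),
# 3 tumor (sphere inside WM)
phantom_labels <- function(grid_dim) {
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  lab <- array(0L, dim = c(nz, ny, nx))
  ix <- slice.index(lab, 3L); iy <- slice.index(lab, 2L)
  iz <- slice.index(lab, 1L)
  bx <- c(5L, nx - 4L); by <- c(5L, ny - 4L); bz <- c(2L, nz - 1L)
  brain <- ix >= bx[1] & ix <= bx[2] & iy >= by[1] & iy <= by[2] &
    iz >= bz[1] & iz <= bz[2]
  interior <- ix >= bx[1] + 2L & ix <= bx[2] - 2L &
    iy >= by[1] + 2L & iy <= by[2] - 2L & iz >= bz[1] & iz <= bz[2]
  lab[brain] <- 2L                      # GM rim
  lab[interior] <- 1L                   # WM interior
  ctr <- c(x = bx[1] + 7.5, y = by[1] + 7.5, z = (bz[1] + bz[2]) / 2)
  tumor <- interior &
    ((ix - ctr["x"])^2 + (iy - ctr["y"])^2 + (iz - ctr["z"])^2) <= 3.6^2
  lab[tumor] <- 3L
  lab
}

#' Generate a seeded DSC phantom with ground truth
#'
#' Builds the 4D signal series
#' \eqn{S(t) = S_{base} e^{-TE\,c(t)} + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} (clipped at 0, as magnitude
#' images are non-negative), from the class geometry (WM interior, GM
#' rim, tumor sphere on a background) and per-class gamma-variate
#' concentration curves. When `tumor_k2 > 0`, tumor curves are
#' \eqn{c(t) = CBV_{tum}\, g(t) - K_2 \int_0^t \bar c}, with
#' \eqn{\bar c} the noiseless mean curve over non-tumor brain voxels
#' and the integral taken by cumulative trapezoid on the frame grid —
#' exactly the model the correction fits.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `series` (a [dsc_series()] whose brain mask is
#'   the true brain) and `truth`: `labels` (0 bg / 1 WM / 2 GM /
#'   3 tumor), `cbv`, `k1`, `k2` (3D maps), `wm_prob` (0.98 on WM),
#'   `entrance`/`trough`/`exit` (1-based frame indices on the
#'   post-discard axis after the default removal of
#'   `n_discarded = 3` frames), `reference_curve` (noiseless
#'   \eqn{\bar c} on the full frame axis), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_labels(spec$grid_dim)
  sp <- dim(lab)
  nt <- spec$n_frames
  tt <- (seq_len(nt) - 1) * spec$frame_spacing
  g <- gamma_variate_unit(tt, spec$arrival, spec$shape, spec$scale)

  class_cbv <- c(0, spec$cbv[["wm"]], spec$cbv[["gm"]], spec$cbv[["tumor"]])
  cbv_map <- array(class_cbv[lab + 1L], dim = sp)
  base_cls <- c(spec$baseline[["background"]], spec$baseline[["wm"]],
                spec$baseline[["gm"]], spec$baseline[["tumor"]])
  base_map <- array(base_cls[lab + 1L], dim = sp)

  nonenh <- lab == 1L | lab == 2L
  cbar_amp <- mean(cbv_map[nonenh])
  refc <- cbar_amp * g
  cumref <- as.vector(pracma::cumtrapz(tt, refc))

  # frames x voxels concentration
  C <- outer(g, as.vector(cbv_map))
  k1_map <- cbv_map / cbar_amp
  k2_map <- array(0, dim = sp)
  if (spec$tumor_k2 != 0) {
    tum <- as.vector(lab == 3L)
    C[, tum] <- C[, tum] - outer(cumref, rep(spec$tumor_k2, sum(tum)))
    k2_map[lab == 3L] <- spec$tumor_k2
  }
  S <- sweep(exp(-spec$te * C), 2L, as.vector(base_map), "*")
  if (spec$noise_sd > 0)
    S <- S + withr::with_seed(spec$seed,
                              matrix(rnorm(length(S), 0, spec$noise_sd),
                                     nrow = nt))
  S <- pmax(S, 0)
  dim(S) <- c(nt, sp)

  series <- dsc_series(S, te = spec$te,
                       frame_spacing = spec$frame_spacing,
                       brain_mask = lab > 0L,
                       grid = dsc_grid(rev(sp)))

  wm_prob <- array(0, dim = sp)
  wm_prob[lab == 1L] <- 0.98
  wm_prob[lab == 2L] <- 0.40
  wm_prob[lab == 3L] <- 0.05

  # framewise truth timing (full axis), then shifted to the
  # post-discard axis assuming the default removal of 3 frames
  gpk <- which.max(g)
  entrance_full <- max(which(tt <= spec$arrival))
  after <- which(seq_len(nt) > gpk & g <= 0.05 * max(g))
  exit_full <- if (length(after)) min(after) else nt
  nd <- 3L
  truth <- list(labels = lab, cbv = cbv_map, k1 = k1_map, k2 = k2_map,
                wm_prob = wm_prob,
                entrance = entrance_full - nd, trough = gpk - nd,
                exit = exit_full - nd, n_discarded = nd,
                reference_curve = refc, cum_reference = cumref,
                frame_times = tt, spec = spec)
  list(series = series, truth = truth)
}

#' Simulate a subjects-by-raters table under the one-way model
#'
#' Generates `value = subject effect + rater noise` with
#' \eqn{b_i \sim N(0, \sigma_b^2)} and
#' \eqn{e_{ij} \sim N(0, \sigma_w^2)}, the generative model under
#' which \eqn{ICC(1,1) = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sigma_b between-subject SD (>= 0).
#' @param sigma_w within-subject (rater) SD (>= 0).
#' @param k number of raters (default 2).
#' @param seed integer seed.
#' @param grand_mean added to every cell (default 5).
#' @return Numeric `n_subjects x k` matrix.
#' @export
generate_rater_table <- function(n_subjects, sigma_b, sigma_w, k = 2L,
                                 seed = 1L, grand_mean = 5) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (sigma_b < 0 || sigma_w < 0) stop("SDs must be >= 0")
  withr::with_seed(seed, {
    b <- rnorm(n_subjects, 0, sigma_b)
    grand_mean + matrix(b, n_subjects, k) +
      matrix(rnorm(n_subjects * k, 0, sigma_w), n_subjects, k)
  })
}
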