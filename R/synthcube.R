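# ---------------------------------------------------------------------------
# Ground-truthed synthetic hyperspectral video generator.
#
# The scene emulates a drying specimen monitored by a NIR camera: one object
# on a bright background whose pixels mix a dry-matter reference spectrum
# and a water-like constituent with a time-decreasing abundance, while the
# object squeezes horizontally toward the geometry of the last frame
# (the reference), per-frame polynomial baselines drift, the optical
# pathlength varies smoothly across the object, an "unknown" systematic
# spectral component outside the EMSC design fluctuates over time, and
# i.i.d. Gaussian noise is added in the absorbance domain. Every latent the
# analysis pipeline estimates (displacement fields, pathlength map, baseline
# trajectories, constituent abundances, residual subspace) is recorded as
# ground truth.
# ---------------------------------------------------------------------------

#' Configuration for the synthetic hyperspectral video
#'
#' Defaults describe a desk-scale scene: 64 x 48 pixels, 60 channels over
#' 930-2200 nm, 20 frames, a water-like abundance that drops quickly during
#' an initial phase and slowly afterwards, a cumulative horizontal shrink of
#' 0.25\% per frame (~5\% overall), small smooth baseline drifts, a +/-15\%
#' textured pathlength field, one low-amplitude unknown systematic spectral
#' component, and absorbance noise of sd 0.005.
#'
#' @param nx,ny,J,K spatial size, channel count, frame count.
#' @param wl_range wavelength range in nm.
#' @param shrink per-frame horizontal contraction factor (1 = rigid).
#' @param vertical_jitter_sd sd in pixels of the per-frame whole-scene
#'   vertical shift (camera/stage bumps); 0 disables.
#' @param water_start,water_mid,water_end water abundance at frame 1, at the
#'   phase change and at frame K.
#' @param phase_change frame index at which the fast drying phase ends.
#' @param baseline_amp amplitudes `c(a, d, g)` of the per-frame baseline
#'   offset/slope/curvature trajectories.
#' @param pathlength_amp relative amplitude of the textured pathlength field.
#' @param background_b effective pathlength of the background (near-white
#'   table; small but positive).
#' @param unknown_amp amplitude of the unknown systematic component (0
#'   disables it).
#' @param noise_sd absorbance noise standard deviation.
#' @param seed integer seed (mandatory; the generator is deterministic given
#'   the config).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(nx = 64L, ny = 48L, J = 60L, K = 20L,
                         wl_range = c(930, 2200),
                         shrink = 0.9975, vertical_jitter_sd = 0.1,
                         water_start = 0.8, water_mid = 0.35, water_end = 0.25,
                         phase_change = NULL,
                         baseline_amp = c(0.03, 0.02, 0.01),
                         pathlength_amp = 0.15,
                         background_b = 0.05,
                         unknown_amp = 0.03,
                         noise_sd = 0.005,
                         seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  if (is.null(phase_change)) phase_change <- max(1L, as.integer(round(0.4 * K)))
  stopifnot(nx > 8, ny > 8, J > 8, K >= 1, shrink > 0, shrink <= 1,
            noise_sd >= 0, phase_change >= 1, phase_change <= K)
  structure(as.list(environment()), class = "synth_config")
}

gaussian_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Generate the constituent spectra of the synthetic scene
#'
#' Smooth positive Gaussian-mixture profiles on the configured wavelength
#' axis: a broad dry-matter reference and a water-like constituent with two
#' absorption bands (near 1450 and 1940 nm). Pairwise correlation above
#' 0.95 would make the EMSC design nearly rank deficient and is an error.
#'
#' @param config a [synth_config()].
#' @param bands optional named list overriding the band parameters; each
#'   entry is a matrix with columns `center`, `width`, `amplitude` (one row
#'   per band). The first entry is the reference.
#' @return list with `wavelengths`, `reference` (dry-matter profile),
#'   `constituents` (named list; default a single `water` profile), and the
#'   pairwise correlation matrix `correlation`.
#' @export
make_constituents <- function(config, bands = NULL) {
  wl <- seq(config$wl_range[1L], config$wl_range[2L], length.out = config$J)
  if (is.null(bands)) {
    bands <- list(
      dry_matter = cbind(center = c(1210, 1700, 2100),
                         width = c(160, 200, 150),
                         amplitude = c(0.55, 0.75, 0.6)),
      water = cbind(center = c(1450, 1940),
                    width = c(70, 90),
                    amplitude = c(0.7, 1.0)))
  }
  profiles <- lapply(bands, function(bm) {
    bm <- as.matrix(bm)
    if (any(bm[, "width"] <= 0) || any(bm[, "amplitude"] < 0))
      stop("band widths must be positive and amplitudes non-negative")
    rowSums(vapply(seq_len(nrow(bm)), function(i)
      gaussian_band(wl, bm[i, "center"], bm[i, "width"], bm[i, "amplitude"]),
      numeric(length(wl))))
  })
  cm <- stats::cor(do.call(cbind, profiles))
  off <- cm[upper.tri(cm)]
  if (length(off) && any(abs(off) >= 0.95))
    stop(sprintf("constituent spectra are collinear (max |cor| = %.3f >= 0.95)",
                 max(abs(off))))
  list(wavelengths = wl, reference = profiles[[1L]],
       constituents = profiles[-1L], correlation = cm)
}

# smooth random field: white noise blurred by repeated 3x3 smoothing
smooth_field <- function(ny, nx, passes = 8L) {
  m <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (i in seq_len(passes)) m <- smooth3(m)
  m / max(abs(m))
}

# raised-cosine window on [0,1] distance-to-edge, for soft object borders
soft_rect <- function(ny, nx, cx, cy, hw, hh, edge = 2.5) {
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  wx <- pmin(pmax((hw - abs(xs - cx)) / edge, 0), 1)
  wy <- pmin(pmax((hh - abs(ys - cy)) / edge, 0), 1)
  (0.5 - 0.5 * cos(pi * wx)) * (0.5 - 0.5 * cos(pi * wy))
}

#' Generate a synthetic hyperspectral video with full ground truth
#'
#' See the module comment: base maps are defined on the reference geometry
#' (the last frame) and evaluated, for frame `k`, at the contracted
#' coordinates, so the object appears wider in earlier frames and squeezes
#' monotonically toward the reference; the true displacement field of frame
#' `k` on the reference grid is `du = (w_k - 1)(x - cx)`, `dv = jitter_k`,
#' with `w_k = shrink^(k - K) >= 1`.
#'
#' @param config a [synth_config()].
#' @return list with `video` (intensity `video_sequence`), `cal`
#'   (a [calibration_pair()]) and `truth` (class `synth_truth`): noiseless
#'   absorbance video, per-frame displacement fields, abundance maps and
#'   trajectory, pathlength map, baseline trajectories, unknown-component
#'   profile/map/trajectory, object masks, constituent spectra and the
#'   config.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nx <- config$nx; ny <- config$ny; J <- config$J; K <- config$K
  cons <- make_constituents(config)
  wl <- cons$wavelengths
  r <- cons$reference
  s_w <- cons$constituents$water
  f <- seq(-1, 1, length.out = J)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # the region of interest is cropped around the specimen, as a line-scan
  # acquisition of a single sample would be: the object fills most of the
  # field of view, so robust (median-based) frame statistics sit firmly
  # inside the object's intensity mode
  hw <- 0.46 * nx; hh <- 0.46 * ny

  # reference-geometry base maps
  obj <- soft_rect(ny, nx, cx, cy, hw, hh)
  b_map <- config$background_b +
    (1 - config$background_b + config$pathlength_amp * smooth_field(ny, nx)) * obj
  water_map <- (0.6 + 0.4 * smooth_field(ny, nx)) * obj
  unknown_map <- smooth_field(ny, nx) * obj

  # trajectories
  k1 <- config$phase_change
  water_traj <- c(seq(config$water_start, config$water_mid, length.out = k1),
                  if (K > k1) seq(config$water_mid, config$water_end,
                                  length.out = K - k1 + 1L)[-1L])
  a_traj <- config$baseline_amp[1L] * sin(2 * pi * seq_len(K) / K)
  d_traj <- config$baseline_amp[2L] * (seq_len(K) - 1) / max(K - 1, 1) -
    config$baseline_amp[2L] / 2
  g_traj <- config$baseline_amp[3L] * cos(2 * pi * seq_len(K) / K)
  unknown_traj <- if (config$unknown_amp > 0)
    config$unknown_amp * sin(2 * pi * (seq_len(K) - 1) / max(K - 1, 1) * 1.5)
  else rep(0, K)
  jitter <- if (config$vertical_jitter_sd > 0)
    stats::rnorm(K, 0, config$vertical_jitter_sd) else rep(0, K)
  jitter[K] <- 0

  # unknown systematic spectral profile, outside the EMSC design: a narrow
  # feature between the water bands, orthogonalised against nothing (EMSC
  # absorbs its projection; the remainder is the residual-subspace truth)
  unknown_spec <- gaussian_band(wl, 1600, 45, 1)

  w_k <- config$shrink^(seq_len(K) - K)          # widening factor, w_K = 1
  # soft_rect support is exactly |x - cx| <= hw (the edge taper lies inside)
  if (hw * max(w_k) >= nx / 2 - 1)
    stop("shrink factor pushes the object out of frame")

  xs0 <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys0 <- matrix(rep(seq_len(ny), times = nx), ny, nx)

  # synthetic calibration cubes: structured but noise-free
  dark_vals <- array(rep(500 + 20 * sin(seq_len(J) / 4), each = ny * nx),
                     dim = c(ny, nx, J))
  white_vals <- array(rep(4000 + 300 * cos(seq_len(J) / 7), each = ny * nx),
                      dim = c(ny, nx, J)) +
    array(rep(as.vector(50 * smooth_field(ny, nx)), times = J),
          dim = c(ny, nx, J))
  dark <- hyper_cube(dark_vals, wl, "intensity")
  white <- hyper_cube(white_vals, wl, "intensity")
  cal <- calibration_pair(dark, white)

  sample_map <- function(m, xs, ys) {
    out <- bilinear_sample(m, xs, ys)
    attr(out, "inbounds") <- NULL
    out
  }

  frames <- vector("list", K)
  noiseless <- vector("list", K)
  fields <- vector("list", K)
  abundance <- array(NA_real_, c(ny, nx, K))
  masks <- vector("list", K)
  for (k in seq_len(K)) {
    # frame-k coordinates -> reference coordinates (inverse of the squeeze)
    xr <- cx + (xs0 - cx) / w_k[k]
    yr <- ys0 - jitter[k]
    bF <- sample_map(b_map, xr, yr)
    wF <- sample_map(water_map, xr, yr) * water_traj[k]
    uF <- sample_map(unknown_map, xr, yr) * unknown_traj[k]
    oF <- sample_map(obj, xr, yr)
    A <- outer(bF, r) + outer(wF, s_w) + outer(uF, unknown_spec)
    A <- A + rep(a_traj[k] + d_traj[k] * f + g_traj[k] * f^2, each = ny * nx)
    A <- array(A, c(ny, nx, J))
    noiseless[[k]] <- hyper_cube(A, wl, "absorbance", frame_index = k)
    if (config$noise_sd > 0)
      A <- A + array(stats::rnorm(length(A), 0, config$noise_sd), dim(A))
    # invert the absorbance and reflectance transforms to intensity counts
    R <- 10^(-A)
    I <- dark_vals + R * (white_vals - dark_vals)
    frames[[k]] <- hyper_cube(I, wl, "intensity", frame_index = k)
    du <- (w_k[k] - 1) * (xs0 - cx)
    dv <- matrix(jitter[k], ny, nx)
    fields[[k]] <- motion_field(du, dv, frame_index = k)
    abundance[, , k] <- matrix(wF, ny, nx)
    masks[[k]] <- matrix(oF, ny, nx) > 0.5
  }
  truth <- structure(list(
    abundance = abundance, abundance_trajectory = water_traj,
    displacement_fields = fields, pathlength_map = b_map,
    baseline = cbind(a = a_traj, d = d_traj, g = g_traj),
    unknown_profile = unknown_spec, unknown_map = unknown_map,
    unknown_trajectory = unknown_traj,
    vertical_jitter = jitter,
    object_mask = obj > 0.5, object_masks = masks,
    noiseless = video_sequence(noiseless),
    reference = r, water = s_w, wavelengths = wl,
    config = config), class = "synth_truth")
  list(video = video_sequence(frames), cal = cal, truth = truth)
}
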