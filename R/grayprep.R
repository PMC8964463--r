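# ---------------------------------------------------------------------------
# Greyscale sequence preparation for motion estimation.
#
# Baseline and scatter fluctuations (illumination drift, angular effects)
# bias optical flow if left in. Each absorbance frame is therefore
# pre-corrected with EMSC coefficients fitted once on the frame-mean
# spectrum, reduced to a single channel by averaging a few temporally stable
# bands, and finally level/range-adjusted against the reference frame.
# ---------------------------------------------------------------------------

#' Pre-correct a frame with frame-mean EMSC coefficients
#'
#' Fits the EMSC model once to the frame's mean spectrum (over valid pixels)
#' and applies the full correction
#' `(x - a - d f - g f^2)/b - sum_i (h_i/b) s_i` to every pixel, so that a
#' frame-wide baseline shift, pathlength change or constituent swing cannot
#' masquerade as motion. Pixel-level heterogeneity is preserved up to the
#' common `1/b` scaling.
#'
#' @param frame a `hyper_cube` in absorbance units.
#' @param model an [emsc_model()] (typically reference + one constituent,
#'   identity weights).
#' @param b_floor positivity floor for the frame pathlength (default `1e-3`).
#' @return the corrected `hyper_cube`, with the fitted frame coefficients in
#'   `meta$frame_emsc`.
#' @export
precorrect_frame <- function(frame, model, b_floor = 1e-3) {
  stopifnot(inherits(frame, "hyper_cube"), inherits(model, "emsc_model"))
  if (frame$unit != "absorbance")
    stop("precorrection expects an absorbance frame")
  d <- cube_dim(frame)
  X <- matrix(frame$values, d[1L] * d[2L], d[3L])
  idx <- which(frame$valid)
  if (!length(idx)) stop("frame has no valid pixels")
  mean_spec <- colMeans(X[idx, , drop = FALSE])
  fit <- emsc_fit(mean_spec, model)
  cf <- fit$coefficients[1L, ]
  if (!is.finite(cf["b"]) || cf["b"] < b_floor)
    stop(sprintf("frame pathlength b = %.3g below floor %g", cf["b"], b_floor))
  base <- drop(baseline_of(fit, model))
  Xc <- sweep(X, 2L, base, "-") / cf["b"]
  if (ncol(model$constituents)) {
    h <- cf[paste0("h_", model$constituent_names)]
    Xc <- Xc - matrix(1, nrow(Xc), 1) %*% t(model$constituents %*% (h / cf["b"]))
  }
  meta <- frame$meta
  meta$frame_emsc <- cf
  hyper_cube(array(Xc, d), frame$wavelengths, unit = "absorbance",
             frame_index = frame$frame_index, valid = frame$valid, meta = meta)
}

#' Select temporally stable wavelength bands
#'
#' Ranks channels by the standard deviation, across time, of the
#' frame-averaged spectrum, and returns the `n_bands` most stable ones.
#' Ties are broken deterministically toward the lower wavelength. These are
#' the bands whose average forms the greyscale image driving motion
#' estimation: they carry spatial texture but minimal temporal chemistry.
#'
#' @param video a `video_sequence` in absorbance units.
#' @param n_bands number of channels to return (default 3).
#' @param force_wavelengths optional vector of wavelengths (nm) overriding
#'   the data-driven choice; matched exactly against the video's axis.
#' @return integer vector of channel indices, ordered as selected.
#' @export
select_stable_bands <- function(video, n_bands = 3L, force_wavelengths = NULL) {
  stopifnot(inherits(video, "video_sequence"))
  wl <- video$frames[[1L]]$wavelengths
  if (!is.null(force_wavelengths))
    return(match_wavelengths(wl, force_wavelengths))
  J <- length(wl)
  if (n_bands < 1L || n_bands > J)
    stop(sprintf("n_bands must be between 1 and %d", J))
  means <- t(vapply(video$frames, function(f) {
    d <- cube_dim(f)
    X <- matrix(f$values, d[1L] * d[2L], d[3L])
    colMeans(X[which(f$valid), , drop = FALSE])
  }, numeric(J)))
  s <- apply(means, 2L, stats::sd)
  # order() is stable: equal deviations resolve to the earlier (lower) channel
  order(s)[seq_len(n_bands)]
}

#' Collapse a frame to greyscale over selected bands
#'
#' Per-pixel mean of the absorbance values at the selected channels; the
#' validity mask is inherited. Invariant under permutation of the band list.
#'
#' @param frame a `hyper_cube`.
#' @param band_indices non-empty vector of channel indices.
#' @return a [gray_frame()].
#' @export
to_grayscale <- function(frame, band_indices) {
  stopifnot(inherits(frame, "hyper_cube"))
  band_indices <- as.integer(band_indices)
  d <- cube_dim(frame)
  if (!length(band_indices)) stop("band index list is empty")
  if (any(band_indices < 1L | band_indices > d[3L]))
    stop("band index out of range")
  g <- apply(frame$values[, , band_indices, drop = FALSE], c(1, 2), mean)
  gray_frame(g, frame$valid, frame$frame_index)
}

#' Level- and range-adjust a grey frame against the reference
#'
#' Aligns the robust intensity statistics of a frame with the reference's:
#' `I_adj = (I - med_k) * (rms_ref / rms_k) + med_ref`, where `med` is the
#' median over valid pixels and `rms = sqrt(median((I - med)^2))` the
#' root-median-squared deviation. After adjustment the frame's median and
#' rms equal the reference's; the operation is idempotent and maps any
#' affine distortion of the reference back onto it exactly.
#'
#' @param frame,ref [gray_frame()] objects; both must have `rms > 0`.
#' @return the adjusted `gray_frame`.
#' @export
level_range_adjust <- function(frame, ref) {
  stopifnot(inherits(frame, "gray_frame"), inherits(ref, "gray_frame"))
  if (!is.finite(ref$stats["rms"]) || ref$stats["rms"] <= 0)
    stop("reference frame has zero or undefined rms")
  if (!is.finite(frame$stats["rms"]) || frame$stats["rms"] <= 0)
    stop(sprintf("frame %d is constant (rms = 0); cannot range-adjust",
                 frame$frame_index))
  v <- (frame$values - frame$stats["median"]) *
    (ref$stats["rms"] / frame$stats["rms"]) + ref$stats["median"]
  gray_frame(v, frame$valid, frame$frame_index)
}

#' Build the full motion-estimation greyscale sequence
#'
#' Runs [precorrect_frame()], [select_stable_bands()], [to_grayscale()] and
#' [level_range_adjust()] over a calibrated absorbance video.
#'
#' @param video a `video_sequence` in absorbance units.
#' @param model an [emsc_model()] for the per-frame pre-correction.
#' @param reference_frame index of the reference frame; negative values count
#'   from the end (default `-1`, the last frame).
#' @param n_bands,force_wavelengths see [select_stable_bands()].
#' @return list with `grays` (list of adjusted `gray_frame`s), `reference`
#'   (the reference `gray_frame`), `ref_index`, `band_indices`, and
#'   `frame_emsc` (K x p matrix of the frame-mean EMSC coefficients).
#' @export
grayscale_sequence <- function(video, model, reference_frame = -1L,
                               n_bands = 3L, force_wavelengths = NULL) {
  K <- n_frames(video)
  ref_index <- if (reference_frame < 0) K + 1L + as.integer(reference_frame)
               else as.integer(reference_frame)
  if (ref_index < 1L || ref_index > K)
    stop(sprintf("reference frame %d outside 1..%d", reference_frame, K))
  # stable bands are judged on the uncorrected absorbance video: after the
  # per-frame pre-correction every channel's frame mean is flat over time, so
  # the ranking would be noise-driven (and could land on a constituent band,
  # breaking brightness constancy for the flow)
  bands <- select_stable_bands(video, n_bands, force_wavelengths)
  pre <- lapply(video$frames, precorrect_frame, model = model)
  grays0 <- lapply(pre, to_grayscale, band_indices = bands)
  ref <- grays0[[ref_index]]
  grays <- lapply(grays0, level_range_adjust, ref = ref)
  frame_emsc <- t(vapply(pre, function(f) f$meta$frame_emsc,
                         numeric(length(model$coef_names))))
  colnames(frame_emsc) <- model$coef_names
  list(grays = grays, reference = grays[[ref_index]], ref_index = ref_index,
       band_indices = bands, frame_emsc = frame_emsc)
}
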