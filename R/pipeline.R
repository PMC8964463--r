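# ---------------------------------------------------------------------------
# End-to-end orchestration: calibrate -> greyscale prep -> motion
# estimation/compensation -> pixel-wise EMSC -> streaming subspace modelling
# of the residuals -> temporal / spectral / spatial summaries.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param reference_frame reference frame index (negative counts from the
#'   end; default -1, the last frame).
#' @param n_gray_bands number of stable bands for the greyscale conversion.
#' @param forced_band_wavelengths optional wavelengths (nm) overriding the
#'   stable-band selection.
#' @param reflectance_floor floor before the log10 transform.
#' @param flow [flow_params()] for motion estimation.
#' @param max_disp displacement validity threshold in pixels (`NULL`: 10\%
#'   of the smaller image side).
#' @param motion_rank,intensity_rank ranks of the motion / intensity
#'   bilinear models (default 2).
#' @param variance_target,block_size,refine_every,outlier_limit streaming
#'   subspace settings, see [otfp_new()].
#' @param emsc_average `"pixel"` or `"mean_spectrum"`, see
#'   [emsc_fit_video()].
#' @param b_floor pathlength floor for pixel fits.
#' @param seed seed recorded in the provenance (the pipeline itself draws no
#'   random numbers).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_frame = -1L, n_gray_bands = 3L,
                            forced_band_wavelengths = NULL,
                            reflectance_floor = 1e-6,
                            flow = flow_params(), max_disp = NULL,
                            motion_rank = 2L, intensity_rank = 2L,
                            variance_target = 0.99, block_size = 4096L,
                            refine_every = 16L, outlier_limit = 6,
                            emsc_average = "pixel", b_floor = 1e-3,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full hyperspectral-video analysis pipeline
#'
#' Stages, in order: (1) radiometric calibration to apparent absorbance;
#' (2) greyscale preparation (frame-mean EMSC pre-correction, stable-band
#' averaging, level/range adjustment against the reference frame);
#' (3) dense optical flow of every grey frame against the reference,
#' displacement validity masking, and back-morphing of every hypercube so
#' all frames share the reference geometry; (4) pixel-wise EMSC on the
#' motion-compensated absorbance spectra of the valid pixels; (5) streaming
#' subspace modelling of the pathlength-corrected EMSC residual stream (one
#' block per frame); (6) summaries: bilinear motion/intensity models,
#' frame-averaged EMSC coefficient and subspace-score trajectories,
#' reconstruction and its PCA.
#'
#' Deterministic: identical inputs and config give a bit-identical report.
#'
#' @param video intensity `video_sequence`.
#' @param cal a [calibration_pair()].
#' @param reference length-J reference spectrum (e.g. dry matter).
#' @param constituents named list of length-J constituent spectra.
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`; see the elements documented
#'   in the individual stage functions, plus `provenance`.
#' @export
pipeline_run <- function(video, cal, reference, constituents,
                         config = pipeline_config()) {
  stopifnot(inherits(video, "video_sequence"),
            inherits(cal, "calibration_pair"))
  K <- n_frames(video)
  d <- cube_dim(video$frames[[1L]])
  wl <- video$frames[[1L]]$wavelengths

  # 1. calibration
  absorb <- calibrate_video(video, cal, floor = config$reflectance_floor)

  # 2. greyscale prep
  model <- emsc_model(reference, constituents, wavelengths = wl)
  gs <- grayscale_sequence(absorb, model,
                           reference_frame = config$reference_frame,
                           n_bands = config$n_gray_bands,
                           force_wavelengths = config$forced_band_wavelengths)

  # 3. motion estimation + compensation
  max_disp <- if (is.null(config$max_disp)) 0.1 * min(d[1:2]) else config$max_disp
  fields <- vector("list", K)
  masks <- vector("list", K)
  warped <- vector("list", K)
  warped_gray <- vector("list", K)
  for (k in seq_len(K)) {
    fields[[k]] <- if (k == gs$ref_index)
      motion_field(matrix(0, d[1L], d[2L]), matrix(0, d[1L], d[2L]),
                   frame_index = k)
    else estimate_flow(gs$grays[[k]], gs$reference, config$flow)
    masks[[k]] <- validity_mask(fields[[k]], max_disp)
    wc <- warp_to_reference(absorb$frames[[k]], fields[[k]])
    masks[[k]] <- masks[[k]] & wc$valid
    warped[[k]] <- wc
    warped_gray[[k]] <- warp_to_reference(gs$grays[[k]], fields[[k]])
  }
  warped_video <- video_sequence(warped)

  # 4. pixel-wise EMSC on motion-compensated spectra
  ef <- emsc_fit_video(warped_video, model, masks,
                       average = config$emsc_average, b_floor = config$b_floor)

  # 5. streaming subspace model of the residual stream, one block per frame
  # residual directions smaller than rounding error on the absorbance scale
  # are numerical noise, not "unknown systematic variation"
  data_scale <- mean(absorb$frames[[1L]]$values^2)
  otfp <- otfp_new(d[3L], variance_target = config$variance_target,
                   block_size = config$block_size,
                   refine_every = config$refine_every,
                   outlier_limit = config$outlier_limit,
                   min_component_variance = 1e-18 * data_scale)
  block_of_frame <- integer(K)
  for (k in seq_len(K)) {
    E <- ef$residual_frames[[k]]
    if (nrow(E)) {
      otfp <- otfp_process_block(otfp, E)
      block_of_frame[k] <- length(otfp$blocks)
    } else block_of_frame[k] <- NA_integer_
  }
  otfp <- otfp_refine(otfp)
  A <- otfp_rank(otfp)
  score_tab <- matrix(NA_real_, K, A)
  for (k in seq_len(K)) {
    if (!is.na(block_of_frame[k]) && A > 0L)
      score_tab[k, ] <- colMeans(otfp$blocks[[block_of_frame[k]]]$scores)
  }

  # 6a. dual-domain bilinear models (uncentred: the reference frame's motion
  # score row is exactly zero)
  MM <- motion_matrix(fields, masks)
  motion_model <- fit_bilinear(MM, rank = min(config$motion_rank, K),
                               center = FALSE)
  # horizontal and vertical motions are also summarised separately: the two
  # directions have distinct physics (squeeze vs stage/camera bumps)
  npx <- d[1L] * d[2L]
  motion_model_h <- fit_bilinear(MM[, seq_len(npx), drop = FALSE],
                                 rank = min(config$motion_rank, K),
                                 center = FALSE)
  motion_model_v <- fit_bilinear(MM[, npx + seq_len(npx), drop = FALSE],
                                 rank = min(config$motion_rank, K),
                                 center = FALSE)
  dI <- t(vapply(seq_len(K), function(k) {
    v <- warped_gray[[k]]$values - gs$reference$values
    v[!(warped_gray[[k]]$valid & gs$reference$valid)] <- 0
    as.vector(v)
  }, numeric(d[1L] * d[2L])))
  intensity_model <- fit_bilinear(dI, rank = min(config$intensity_rank, K),
                                  center = FALSE)

  # 6b. pathlength-corrected reconstruction and its PCA
  recon <- reconstructed_spectra(ef, otfp, block_of_frame, model)
  pca <- pca_of_reconstruction(recon$frame_mean)

  # conservation bookkeeping: energy of the post-EMSC (scatter-corrected)
  # data vs energy left after the subspace stage
  energy <- conservation_energy(ef, otfp, block_of_frame, model)

  structure(list(
    frame_coefficients = ef$frame_coefficients,
    coefficient_maps = ef$maps,
    otfp = otfp, otfp_scores = score_tab, block_of_frame = block_of_frame,
    motion_model = motion_model, motion_model_h = motion_model_h,
    motion_model_v = motion_model_v, intensity_model = intensity_model,
    fields = fields, masks = masks,
    grays = gs$grays, reference_gray = gs$reference,
    ref_index = gs$ref_index, band_indices = gs$band_indices,
    frame_emsc = gs$frame_emsc,
    reconstruction = recon, pca = pca,
    energy = energy,
    excluded_per_frame = vapply(masks, function(m) sum(!m), integer(1L)),
    emsc_model = model,
    provenance = list(config = config, seed = config$seed,
                      dims = c(d, K), wavelengths = wl)),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  d <- x$provenance$dims
  cat(sprintf("<pipeline_report> %d x %d x %d, K=%d; subspace rank %d; EMSC coefficients: %s\n",
              d[1L], d[2L], d[3L], d[4L], otfp_rank(x$otfp),
              paste(colnames(x$frame_coefficients), collapse = ", ")))
  invisible(x)
}

# per-pixel pathlength-corrected reconstruction r + sum dc_i s_i + e_hat and
# its frame averages over valid pixels
reconstructed_spectra <- function(ef, otfp, block_of_frame, model) {
  K <- length(ef$residual_frames)
  J <- length(model$reference)
  frame_mean <- matrix(NA_real_, K, J)
  for (k in seq_len(K)) {
    idx <- ef$pixel_index[[k]]
    if (!length(idx)) next
    b <- ef$maps[["b"]][, , k][idx]
    H <- vapply(model$constituent_names, function(nm)
      ef$maps[[paste0("h_", nm)]][, , k][idx], numeric(length(idx)))
    chem <- (as.matrix(H) / b) %*% t(model$constituents)
    e_hat <- if (!is.na(block_of_frame[k]) && otfp_rank(otfp) > 0L)
      otfp_reconstruct(otfp, block_of_frame[k])
    else matrix(rep(otfp$center, each = length(idx)), length(idx), J)
    Xp <- matrix(model$reference, length(idx), J, byrow = TRUE) + chem + e_hat
    frame_mean[k, ] <- colMeans(Xp)
  }
  list(frame_mean = frame_mean)
}

# energy of the scatter-corrected spectra about their grand mean, and energy
# unexplained after the subspace stage
conservation_energy <- function(ef, otfp, block_of_frame, model) {
  K <- length(ef$residual_frames)
  ss_post <- 0; n_rows <- 0; col_sum <- 0
  ss_unexplained <- 0
  for (k in seq_len(K)) {
    idx <- ef$pixel_index[[k]]
    if (!length(idx)) next
    b <- ef$maps[["b"]][, , k][idx]
    coeffs <- vapply(model$coef_names, function(nm)
      ef$maps[[nm]][, , k][idx], numeric(length(idx)))
    # scatter-corrected spectrum = r + sum (h_i/b) s_i + e/b
    H <- coeffs[, grep("^h_", model$coef_names), drop = FALSE]
    chem <- if (ncol(H)) (H / b) %*% t(model$constituents) else 0
    Xp <- matrix(model$reference, length(idx), length(model$reference),
                 byrow = TRUE) + chem + ef$residual_frames[[k]]
    ss_post <- ss_post + sum(Xp^2)
    col_sum <- col_sum + colSums(Xp)
    n_rows <- n_rows + length(idx)
    e_hat <- if (!is.na(block_of_frame[k]) && otfp_rank(otfp) > 0L)
      otfp_reconstruct(otfp, block_of_frame[k])
    else matrix(rep(otfp$center, each = length(idx)),
                length(idx), length(model$reference))
    ss_unexplained <- ss_unexplained + sum((ef$residual_frames[[k]] - e_hat)^2)
  }
  grand_mean <- col_sum / max(n_rows, 1L)
  ss_post_centred <- ss_post - n_rows * sum(grand_mean^2)
  list(post_emsc_ss = ss_post_centred, unexplained_ss = ss_unexplained,
       ratio = ss_unexplained / ss_post_centred)
}

#' Mean-centred PCA of the frame-averaged reconstructed spectra
#'
#' Standard PCA (two components by default) of the `K x J` matrix of
#' frame-averaged, pathlength-corrected reconstructed spectra; the score
#' trajectory traces the temporal phases of the process.
#'
#' @param frame_mean `K x J` matrix (rows with `NA` are dropped from the fit
#'   and returned as `NA` scores).
#' @param rank number of components (default 2).
#' @return list with `scores` (`K x rank`), `loadings` (`J x rank`),
#'   `explained_variance`, `center`.
#' @export
pca_of_reconstruction <- function(frame_mean, rank = 2L) {
  frame_mean <- as.matrix(frame_mean)
  ok <- stats::complete.cases(frame_mean)
  if (sum(ok) < 3L) stop("need at least 3 frames for the reconstruction PCA")
  m <- fit_bilinear(frame_mean[ok, , drop = FALSE], rank = min(rank, sum(ok)),
                    center = TRUE)
  scores <- matrix(NA_real_, nrow(frame_mean), m$rank)
  scores[ok, ] <- m$scores
  list(scores = scores, loadings = m$loadings,
       explained_variance = m$explained_variance, center = m$center)
}

#' Spatial maps of EMSC coefficients and subspace scores
#'
#' Extracts, for the requested frames, the per-pixel EMSC coefficient maps
#' and the per-pixel subspace score maps, with excluded pixels carried as
#' `NA` (rendered black when written to PNG).
#'
#' @param report a [pipeline_run()] report.
#' @param frames frame indices (default: all).
#' @param dir optional directory; when given, each map is also written as a
#'   greyscale PNG (masked pixels black) named `<what>_frame<k>.png`.
#' @return nested list `maps[[what]][[frame]]` of `Ny x Nx` matrices.
#' @export
summarize_maps <- function(report, frames = NULL, dir = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  K <- nrow(report$frame_coefficients)
  if (is.null(frames)) frames <- seq_len(K)
  if (any(frames < 1L | frames > K)) stop("frame index out of range")
  d <- report$provenance$dims
  out <- list()
  A <- otfp_rank(report$otfp)
  for (cf in names(report$coefficient_maps))
    out[[cf]] <- lapply(frames, function(k) report$coefficient_maps[[cf]][, , k])
  if (A > 0L) {
    for (a in seq_len(A)) {
      out[[paste0("score_", a)]] <- lapply(frames, function(k) {
        m <- matrix(NA_real_, d[1L], d[2L])
        g <- report$block_of_frame[k]
        if (!is.na(g)) {
          idx <- which(report$masks[[k]])
          m[idx] <- report$otfp$blocks[[g]]$scores[, a]
        }
        m
      })
    }
  }
  for (what in names(out)) names(out[[what]]) <- paste0("frame", frames)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (what in names(out)) for (i in seq_along(frames)) {
      m <- out[[what]][[i]]
      rng <- range(m, na.rm = TRUE)
      img <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0 + 0.5
      img[is.na(img)] <- 0            # excluded pixels render black
      png::writePNG(img, file.path(dir, sprintf("%s_frame%d.png", what,
                                                frames[i])))
    }
  }
  invisible(out)
}

#' Stored-model compression ratio of a pipeline report
#'
#' Scalars retained by the three models (motion and intensity scores +
#' loadings, per-pixel EMSC coefficient maps, subspace scores + loadings +
#' centre) divided by the raw video's scalars.
#'
#' @param report a [pipeline_run()] report.
#' @return list with `stored`, `raw`, `ratio`.
#' @export
compression_summary <- function(report) {
  d <- report$provenance$dims
  raw <- prod(d)
  A <- otfp_rank(report$otfp)
  npx_valid <- sum(vapply(report$masks, sum, integer(1L)))
  stored <- length(report$motion_model$scores) +
    length(report$motion_model$loadings) +
    length(report$intensity_model$scores) +
    length(report$intensity_model$loadings) +
    npx_valid * ncol(report$frame_coefficients) +   # EMSC coefficient maps
    npx_valid * A + A * d[3L] + d[3L]               # subspace model
  list(stored = stored, raw = raw, ratio = stored / raw)
}
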