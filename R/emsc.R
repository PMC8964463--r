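# ---------------------------------------------------------------------------
# Extended Multiplicative Signal Correction.
#
# Model for one absorbance spectrum x (length J):
#
#   x = b*r + sum_i h_i*s_i + a*1 + d*f + g*f^2 + e,     h_i = b * dc_i
#
# r   : reference spectrum (e.g. dry matter)
# s_i : constituent spectra (e.g. pure water)
# f   : J values equally spaced from -1 to +1
# b   : effective relative pathlength (multiplicative scatter term)
# a,d,g : baseline offset, slope, curvature
# dc_i  : abundance deviation of constituent i from the reference state
#
# Coefficients are obtained by (weighted) least squares on the design
# M = [r, s_1..s_I, 1, f, f^2]. For numerical conditioning the reference and
# constituent columns are max-normalised internally; reported coefficients
# are rescaled back to the original profile scale, so b and h_i always refer
# to the profiles the caller supplied.
# ---------------------------------------------------------------------------

#' Build an EMSC model
#'
#' Assembles the design matrix `[r, s_1..s_I, 1, f, f^2]` on a given
#' wavelength axis, where `f` runs linearly from -1 to +1 across the axis and
#' the three polynomial columns absorb smooth baseline level, slope and
#' curvature. Channel weights (diagonal of the weighted-least-squares
#' problem) default to one everywhere.
#'
#' @param reference length-J reference spectrum `r` (e.g. dry matter).
#' @param constituents named list of length-J constituent spectra `s_i`
#'   (e.g. `list(water = s_water)`); may be empty.
#' @param wavelengths length-J wavelength axis, nm (used for labelling and
#'   for matching spectra read from file).
#' @param weights optional length-J non-negative channel weights; default all
#'   ones (ordinary least squares).
#' @param normalize max-normalise `r` and `s_i` internally for conditioning
#'   (reported coefficients are always rescaled to the input profile scale).
#' @return object of class `emsc_model`.
#' @export
emsc_model <- function(reference, constituents = list(), wavelengths = NULL,
                       weights = NULL, normalize = TRUE) {
  r <- as.numeric(reference)
  J <- length(r)
  if (is.null(wavelengths)) wavelengths <- seq_len(J)
  if (length(wavelengths) != J) stop("wavelengths and reference lengths differ")
  if (J <= length(constituents) + 4L)
    stop("need more channels than model terms (J > I + 4)")
  if (!length(constituents)) names(constituents) <- character(0)
  if (length(constituents) && is.null(names(constituents)))
    names(constituents) <- paste0("s", seq_along(constituents))
  S <- if (length(constituents))
    vapply(constituents, function(s) {
      s <- as.numeric(s)
      if (length(s) != J) stop("constituent spectrum length differs from reference")
      s
    }, numeric(J))
  else matrix(numeric(0), J, 0)
  if (is.null(weights)) weights <- rep(1, J)
  weights <- as.numeric(weights)
  if (length(weights) != J || any(weights < 0) || all(weights == 0))
    stop("weights must be length J, non-negative, not all zero")
  f <- seq(-1, 1, length.out = J)
  norms <- c(b = 1, stats::setNames(rep(1, ncol(S)),
                                    paste0("h_", colnames(S))))
  if (normalize) {
    norms["b"] <- max(abs(r))
    if (ncol(S))
      norms[-1L] <- apply(abs(S), 2L, max)
    if (any(norms == 0)) stop("a model profile is identically zero")
  }
  Mn <- cbind(r / norms["b"],
              if (ncol(S)) sweep(S, 2L, norms[-1L], "/"),
              1, f, f^2)
  coef_names <- c("b",
                  if (ncol(S)) paste0("h_", colnames(S)),
                  "a", "d", "g")
  colnames(Mn) <- coef_names
  # rank / collinearity check under the weights
  sw <- sqrt(weights)
  qr_d <- qr(Mn * sw)
  if (qr_d$rank < ncol(Mn)) {
    cc <- suppressWarnings(abs(stats::cor(Mn)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "EMSC design is rank deficient; most collinear columns: '%s' and '%s' (|cor| = %.4f)",
      coef_names[worst[1L]], coef_names[worst[2L]], max(cc)))
  }
  # per-coefficient rescaling from the normalised basis to the input scale
  scale_back <- stats::setNames(rep(1, length(coef_names)), coef_names)
  scale_back[names(norms)] <- norms
  M_orig <- cbind(r, if (ncol(S)) S, 1, f, f^2)
  colnames(M_orig) <- coef_names
  structure(list(reference = r, constituents = S,
                 constituent_names = colnames(S),
                 wavelengths = as.numeric(wavelengths), f = f,
                 weights = weights, design = Mn, design_orig = M_orig,
                 norms = norms, scale_back = scale_back,
                 qr = qr_d, sw = sw, coef_names = coef_names),
            class = "emsc_model")
}

#' @export
print.emsc_model <- function(x, ...) {
  cat(sprintf("<emsc_model> J=%d channels, reference + %d constituent(s) [%s] + 3 baseline terms\n",
              length(x$reference), ncol(x$constituents),
              paste(x$constituent_names, collapse = ", ")))
  invisible(x)
}

as_spectra_matrix <- function(x, J) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != J)
    stop(sprintf("spectra have %d channels; model expects %d", ncol(x), J))
  x
}

#' Fit EMSC coefficients by (weighted) least squares
#'
#' Solves the weighted least-squares problem for one or many spectra at once
#' via a QR decomposition of the weighted design (never the literal inverse
#' of the normal equations). The residual is weight-orthogonal to the design
#' columns; the reconstruction `b*r + sum h_i s_i + a + d f + g f^2 + e`
#' reproduces each input spectrum to machine precision.
#'
#' @param x one spectrum (length J) or an `N x J` matrix of spectra.
#' @param model an [emsc_model()].
#' @return object of class `emsc_fit`: list with `coefficients`
#'   (`N x (I+4)` matrix, columns `b, h_*, a, d, g`), `residuals` (`N x J`),
#'   and `model`.
#' @export
emsc_fit <- function(x, model) {
  stopifnot(inherits(model, "emsc_model"))
  X <- as_spectra_matrix(x, length(model$reference))
  # coefficients in the normalised basis: solve (sw*Mn) beta = sw*x
  B <- t(qr.coef(model$qr, model$sw * t(X)))   # N x p
  # rescale b and h_i back to the caller's profile scale
  B <- sweep(B, 2L, model$scale_back, "/")
  colnames(B) <- model$coef_names
  E <- X - B %*% t(model$design_orig)
  structure(list(coefficients = B, residuals = E, model = model),
            class = "emsc_fit")
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf("<emsc_fit> %d spectrum/spectra, coefficients: %s\n",
              nrow(x$coefficients), paste(colnames(x$coefficients), collapse = ", ")))
  invisible(x)
}

coef_get <- function(coeffs, what) {
  if (inherits(coeffs, "emsc_fit")) coeffs <- coeffs$coefficients
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1L,
                                             dimnames = list(NULL, names(coeffs)))
  if (!all(what %in% colnames(coeffs)))
    stop("coefficient matrix lacks columns: ",
         paste(setdiff(what, colnames(coeffs)), collapse = ", "))
  coeffs[, what, drop = FALSE]
}

baseline_of <- function(coeffs, model) {
  B <- coef_get(coeffs, c("a", "d", "g"))
  B %*% rbind(rep(1, length(model$f)), model$f, model$f^2)
}

check_b_floor <- function(b, b_floor) {
  bad <- !is.finite(b) | abs(b) < b_floor
  if (any(bad))
    warning(sprintf("|b| below floor %g for %d spectrum/spectra; flagged invalid",
                    b_floor, sum(bad)))
  bad
}

#' Remove scatter and baseline effects from spectra
#'
#' `x_corrected = (x - a - d f - g f^2) / b`. Chemical (constituent)
#' contributions are retained: refitting the corrected spectrum returns
#' `b = 1`, `a = d = g = 0` and unchanged abundances `h_i / b`.
#'
#' @param x spectrum or `N x J` matrix that was fitted.
#' @param coeffs an [emsc_fit()] (or its coefficient matrix) for the same rows.
#' @param model the [emsc_model()] used for the fit.
#' @param b_floor spectra with `|b|` below this are flagged in the returned
#'   `"invalid"` attribute (default `1e-3`) and divided anyway.
#' @return corrected matrix of the same shape as `x`, with a logical
#'   `"invalid"` attribute (one flag per spectrum).
#' @export
emsc_correct_scatter <- function(x, coeffs, model, b_floor = 1e-3) {
  X <- as_spectra_matrix(x, length(model$reference))
  b <- drop(coef_get(coeffs, "b"))
  bad <- check_b_floor(b, b_floor)
  out <- (X - baseline_of(coeffs, model)) / b
  attr(out, "invalid") <- bad
  out
}

#' Remove scatter, baseline and known chemical variation
#'
#' `x_corrected = (x - a - d f - g f^2)/b - sum_i (h_i/b) s_i`. For a
#' noise-free model spectrum the output equals the reference `r` exactly.
#'
#' @inheritParams emsc_correct_scatter
#' @return corrected matrix, `"invalid"` attribute as in
#'   [emsc_correct_scatter()].
#' @export
emsc_correct_full <- function(x, coeffs, model, b_floor = 1e-3) {
  out <- emsc_correct_scatter(x, coeffs, model, b_floor)
  if (ncol(model$constituents)) {
    b <- drop(coef_get(coeffs, "b"))
    H <- coef_get(coeffs, paste0("h_", model$constituent_names))
    out <- out - (H / b) %*% t(model$constituents)
  }
  out
}

#' EMSC residuals and pathlength-corrected residuals
#'
#' The raw residual is `e = x - b r - sum h_i s_i - a - d f - g f^2`; when
#' residual structure is assumed to scale with the effective optical
#' pathlength it is divided by `b`, giving the pathlength-corrected residual
#' `e / b` that feeds the streaming subspace stage.
#'
#' @inheritParams emsc_correct_scatter
#' @param pathlength_corrected divide each residual row by its `b`?
#' @return `N x J` residual matrix (with `"invalid"` attribute when
#'   pathlength-corrected).
#' @export
emsc_residual <- function(x, coeffs, model, pathlength_corrected = FALSE,
                          b_floor = 1e-3) {
  X <- as_spectra_matrix(x, length(model$reference))
  if (inherits(coeffs, "emsc_fit")) {
    E <- coeffs$residuals
  } else {
    B <- coef_get(coeffs, model$coef_names)
    E <- X - B %*% t(model$design_orig)
  }
  if (pathlength_corrected) {
    b <- drop(coef_get(coeffs, "b"))
    bad <- check_b_floor(b, b_floor)
    E <- E / b
    attr(E, "invalid") <- bad
  }
  E
}

#' Pixel-wise EMSC over a motion-compensated video
#'
#' Fits the EMSC model to every valid pixel spectrum of every frame and
#' returns (i) the K x (I+4) table of frame-averaged coefficients (mean of
#' the pixel-wise coefficients over each frame's valid pixels — not the fit
#' of the mean spectrum; set `average = "mean_spectrum"` for the
#' alternative), (ii) per-frame spatial coefficient maps, and (iii) the
#' stream of pathlength-corrected residual spectra for the subspace stage.
#'
#' @param video motion-compensated `video_sequence` in absorbance units.
#' @param model an [emsc_model()].
#' @param masks list of K `Ny x Nx` logical masks (from the motion stage)
#'   gating which pixels are processed; `NULL` processes every pixel.
#' @param average `"pixel"` (default) or `"mean_spectrum"`.
#' @param b_floor pathlength floor; pixels below it are invalidated.
#' @return object of class `emsc_video_fit`: list with `frame_coefficients`
#'   (K x p matrix; `NA` rows for all-invalid frames), `maps` (named list of
#'   `Ny x Nx x K` arrays, `NA` at unprocessed pixels), `residual_frames`
#'   (list of per-frame matrices of pathlength-corrected residuals over valid
#'   pixels), `pixel_index` (list of per-frame valid-pixel linear indices),
#'   `masks` (effective masks after the `b` floor), and `model`.
#' @export
emsc_fit_video <- function(video, model, masks = NULL,
                           average = c("pixel", "mean_spectrum"),
                           b_floor = 1e-3) {
  stopifnot(inherits(video, "video_sequence"), inherits(model, "emsc_model"))
  average <- match.arg(average)
  K <- n_frames(video)
  d <- cube_dim(video$frames[[1L]])
  p <- length(model$coef_names)
  frame_tab <- matrix(NA_real_, K, p, dimnames = list(NULL, model$coef_names))
  maps <- stats::setNames(
    rep(list(array(NA_real_, dim = c(d[1L], d[2L], K))), p), model$coef_names)
  residual_frames <- vector("list", K)
  pixel_index <- vector("list", K)
  eff_masks <- vector("list", K)
  for (k in seq_len(K)) {
    frame <- video$frames[[k]]
    mask <- if (is.null(masks)) frame$valid else masks[[k]] & frame$valid
    idx <- which(mask)
    eff_masks[[k]] <- mask
    if (!length(idx)) {
      residual_frames[[k]] <- matrix(numeric(0), 0L, d[3L])
      pixel_index[[k]] <- integer(0)
      next
    }
    X <- matrix(frame$values, d[1L] * d[2L], d[3L])[idx, , drop = FALSE]
    fit <- emsc_fit(X, model)
    bad <- suppressWarnings(check_b_floor(fit$coefficients[, "b"], b_floor))
    if (any(bad)) {
      mask[idx[bad]] <- FALSE
      eff_masks[[k]] <- mask
      idx <- idx[!bad]
      X <- X[!bad, , drop = FALSE]
      fit <- list(coefficients = fit$coefficients[!bad, , drop = FALSE],
                  residuals = fit$residuals[!bad, , drop = FALSE])
    }
    if (!length(idx)) {
      residual_frames[[k]] <- matrix(numeric(0), 0L, d[3L])
      pixel_index[[k]] <- integer(0)
      next
    }
    for (cf in model$coef_names) {
      m <- maps[[cf]][, , k]
      m[idx] <- fit$coefficients[, cf]
      maps[[cf]][, , k] <- m
    }
    frame_tab[k, ] <- if (average == "pixel") {
      colMeans(fit$coefficients)
    } else {
      emsc_fit(colMeans(X), model)$coefficients[1L, ]
    }
    residual_frames[[k]] <- fit$residuals / fit$coefficients[, "b"]
    pixel_index[[k]] <- idx
  }
  structure(list(frame_coefficients = frame_tab, maps = maps,
                 residual_frames = residual_frames, pixel_index = pixel_index,
                 masks = eff_masks, average = average, model = model),
            class = "emsc_video_fit")
}

#' @export
print.emsc_video_fit <- function(x, ...) {
  cat(sprintf("<emsc_video_fit> K=%d frames, %d coefficient maps, %d residual spectra streamed\n",
              nrow(x$frame_coefficients), length(x$maps),
              sum(vapply(x$residual_frames, nrow, integer(1L)))))
  invisible(x)
}
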