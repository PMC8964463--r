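# ---------------------------------------------------------------------------
# Dual-domain bilinear (scores x loadings) models: one over the unfolded
# motion fields (rows = frames, columns = [du | dv] pixels), one over the
# unfolded intensity deviations in reference geometry. Both are truncated
# singular value decompositions with a fixed sign convention.
# ---------------------------------------------------------------------------

fix_signs <- function(scores, loadings) {
  for (a in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Fit a truncated bilinear model to a frames-by-variables matrix
#'
#' Truncated singular value decomposition of the (optionally column-centred)
#' matrix: `X ~ center + T P'` with orthonormal loadings `P` and the best
#' rank-`A` approximation property. Explained variance per component is the
#' fraction of the (centred) total sum of squares. The sign of each
#' component is fixed so its largest-magnitude loading is positive, making
#' runs comparable.
#'
#' For motion input each row is one frame's unfolded `[du | dv]` vector with
#' masked pixels imputed to zero; left uncentred, the reference frame's score
#' row is exactly zero.
#'
#' @param X `K x M` numeric matrix.
#' @param rank requested number of components `A <= min(K, M)`; shrunk with a
#'   warning if it exceeds the matrix rank.
#' @param center subtract column means first? (default `FALSE`).
#' @return object of class `bilinear_model`: `scores` (`K x A`), `loadings`
#'   (`M x A`, orthonormal columns), `center` (length-M), `explained_variance`
#'   (length-A fractions, non-increasing), `singular_values` (all
#'   `min(K, M)`), `rank`.
#' @export
fit_bilinear <- function(X, rank, center = FALSE) {
  X <- as.matrix(X)
  K <- nrow(X); M <- ncol(X)
  if (rank < 0 || rank > min(K, M))
    stop(sprintf("rank must lie in 0..%d", min(K, M)))
  ctr <- if (center) colMeans(X) else rep(0, M)
  Xc <- if (center) sweep(X, 2L, ctr, "-") else X
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  eff_rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0))
  A <- as.integer(rank)
  if (A > eff_rank) {
    warning(sprintf("requested rank %d exceeds matrix rank %d; shrunk", A, eff_rank))
    A <- eff_rank
  }
  if (A == 0L) {
    scores <- matrix(0, K, 0L); loadings <- matrix(0, M, 0L)
  } else {
    scores <- sv$u[, seq_len(A), drop = FALSE] %*% diag(sv$d[seq_len(A)], A)
    loadings <- sv$v[, seq_len(A), drop = FALSE]
    fs <- fix_signs(scores, loadings)
    scores <- fs$scores; loadings <- fs$loadings
  }
  ev <- if (tot > 0) sv$d[seq_len(A)]^2 / tot else rep(0, A)
  structure(list(scores = scores, loadings = loadings, center = ctr,
                 explained_variance = ev, singular_values = sv$d,
                 rank = A, centered = center),
            class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("<bilinear_model> %d x %d, rank %d, EV %s\n",
              nrow(x$scores), nrow(x$loadings), x$rank,
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " + ")))
  invisible(x)
}

#' Reconstruct a row of a bilinear model
#'
#' @param model a [fit_bilinear()] result.
#' @param k row (frame) index.
#' @return numeric vector `center + t_k P'`.
#' @export
bilinear_row <- function(model, k) {
  if (k < 1L || k > nrow(model$scores)) stop("unknown row index")
  if (model$rank == 0L) return(model$center)
  model$center + drop(model$loadings %*% model$scores[k, ])
}

#' Stack motion fields into the rows of the motion matrix
#'
#' Each row is one frame's `[du | dv]` unfolded in the package's raster
#' order (y fastest, then x), with invalid pixels imputed to zero.
#'
#' @param fields list of K [motion_field()] objects.
#' @param masks optional list of K logical masks further gating validity.
#' @return `K x (2 Ny Nx)` matrix.
#' @export
motion_matrix <- function(fields, masks = NULL) {
  K <- length(fields)
  t(vapply(seq_len(K), function(k) {
    f <- fields[[k]]
    ok <- if (is.null(masks)) f$valid else f$valid & masks[[k]]
    du <- f$du; dv <- f$dv
    du[!ok] <- 0; dv[!ok] <- 0
    c(as.vector(du), as.vector(dv))
  }, numeric(2L * length(fields[[1L]]$du))))
}

#' Rebuild a video frame from its motion and intensity models
#'
#' Composes the reference image with the modelled intensity deviation (both
#' in reference geometry), then displaces the result by the modelled motion
#' field to render frame `k` in its own geometry. The modelled forward field
#' is inverted by fixed-point iteration so the rendering can use backward
#' bilinear sampling. At full rank and exact flow the reconstruction matches
#' the original frame on valid pixels to within interpolation error.
#'
#' @param k frame index.
#' @param motion_model [fit_bilinear()] model of the motion matrix
#'   (`K x 2NyNx`).
#' @param intensity_model [fit_bilinear()] model of the intensity deviations
#'   (`K x NyNx`, reference geometry).
#' @param ref the reference [gray_frame()].
#' @return a `gray_frame`; pixels sampling outside the frame are invalid.
#' @export
reconstruct_frame <- function(k, motion_model, intensity_model, ref) {
  stopifnot(inherits(ref, "gray_frame"))
  if (nrow(motion_model$scores) != nrow(intensity_model$scores))
    stop("motion and intensity models disagree on the number of frames")
  ny <- nrow(ref$values); nx <- ncol(ref$values)
  dI <- matrix(bilinear_row(intensity_model, k), ny, nx)
  L <- ref$values + dI
  mo <- bilinear_row(motion_model, k)
  fld <- motion_field(matrix(mo[seq_len(ny * nx)], ny, nx),
                      matrix(mo[ny * nx + seq_len(ny * nx)], ny, nx),
                      frame_index = k)
  if (all(fld$du == 0) && all(fld$dv == 0))
    return(gray_frame(L, ref$valid, k))
  inv <- invert_field(fld)
  co <- warp_coords(inv)
  s <- bilinear_sample(L, co$xs, co$ys)
  inb <- attr(s, "inbounds"); attr(s, "inbounds") <- NULL
  gray_frame(s, inb, k)
}
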