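# ---------------------------------------------------------------------------
# Dense motion estimation and compensation.
#
# Displacement convention: a motion_field (du, dv) lives on the reference
# pixel grid and maps reference coordinates to frame-k coordinates,
# O_k = O_ref + delta-O_k. Back-morphing therefore samples frame k at
# (x + du, y + dv) for every reference pixel (x, y): after warping, objects
# occupy their reference-frame positions.
# ---------------------------------------------------------------------------

#' Motion field constructor
#'
#' @param du,dv `Ny x Nx` numeric matrices: horizontal (x) and vertical (y)
#'   displacement in pixels from reference geometry to frame geometry.
#' @param valid optional `Ny x Nx` logical; default marks pixels whose
#'   displaced sampling location lies inside the frame.
#' @param frame_index integer frame index the field belongs to.
#' @return object of class `motion_field`.
#' @export
motion_field <- function(du, dv, valid = NULL, frame_index = 1L) {
  du <- as.matrix(du); dv <- as.matrix(dv)
  if (!identical(dim(du), dim(dv))) stop("du and dv differ in shape")
  ny <- nrow(du); nx <- ncol(du)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) + du
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx) + dv
  inside <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  if (is.null(valid)) valid <- inside else valid <- as.matrix(valid) & inside
  if (any(!is.finite(du[valid])) || any(!is.finite(dv[valid])))
    stop("non-finite displacements on valid pixels")
  structure(list(du = du, dv = dv, valid = valid,
                 frame_index = as.integer(frame_index)),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  mag <- sqrt(x$du^2 + x$dv^2)
  cat(sprintf("<motion_field> %d x %d, frame %d, |d| mean %.3f px, %.1f%% valid\n",
              nrow(x$du), ncol(x$du), x$frame_index, mean(mag[x$valid]),
              100 * mean(x$valid)))
  invisible(x)
}

#' Grey frame constructor
#'
#' A single-channel image derived from a hyperspectral frame, with a
#' validity mask and robust level/spread statistics (median and
#' root-median-squared deviation) computed over valid pixels.
#'
#' @param values `Ny x Nx` numeric matrix.
#' @param valid optional logical mask.
#' @param frame_index integer.
#' @return object of class `gray_frame` with a `stats` element
#'   `c(median, rms)` where `rms = sqrt(median((I - median(I))^2))`.
#' @export
gray_frame <- function(values, valid = NULL, frame_index = 1L) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  valid <- as.matrix(valid) & is.finite(values)
  v <- values[valid]
  med <- if (length(v)) stats::median(v) else NA_real_
  rms <- if (length(v)) sqrt(stats::median((v - med)^2)) else NA_real_
  structure(list(values = values, valid = valid,
                 frame_index = as.integer(frame_index),
                 stats = c(median = med, rms = rms)),
            class = "gray_frame")
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame> %d x %d, frame %d, median %.4g, rms %.4g\n",
              nrow(x$values), ncol(x$values), x$frame_index,
              x$stats["median"], x$stats["rms"]))
  invisible(x)
}

# --- bilinear sampling -------------------------------------------------------

# Sample img at continuous coordinates (xs, ys) (1-based, x = column).
# Out-of-bounds locations are clamped for the value but reported in the
# `inbounds` attribute.
bilinear_sample <- function(img, xs, ys) {
  ny <- nrow(img); nx <- ncol(img)
  inb <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  xs <- pmin(pmax(xs, 1), nx)
  ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); y0 <- pmin(floor(ys), ny - 1L)
  if (nx == 1L) x0[] <- 1L
  if (ny == 1L) y0[] <- 1L
  fx <- xs - x0; fy <- ys - y0
  i00 <- (x0 - 1) * ny + y0
  v <- (1 - fx) * (1 - fy) * img[i00] +
       (1 - fx) * fy       * img[i00 + (ny > 1L)] +
       fx       * (1 - fy) * img[i00 + ny * (nx > 1L)] +
       fx       * fy       * img[i00 + ny * (nx > 1L) + (ny > 1L)]
  out <- matrix(v, nrow(as.matrix(xs)), ncol(as.matrix(xs)))
  attr(out, "inbounds") <- matrix(inb, nrow(out), ncol(out))
  out
}

# Interpolation weight bundle shared across channels of a cube warp.
warp_coords <- function(field) {
  ny <- nrow(field$du); nx <- ncol(field$du)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) + field$du
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx) + field$dv
  list(xs = xs, ys = ys)
}

# --- Horn-Schunck optical flow ----------------------------------------------

shift_img <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
  xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
  m[yi, xi, drop = FALSE]
}

smooth3 <- function(m) {
  (shift_img(m, -1, 0) + shift_img(m, 1, 0) + shift_img(m, 0, -1) +
     shift_img(m, 0, 1) + 4 * m) / 8
}

pyr_down <- function(m) {
  s <- smooth3(smooth3(m))
  s[seq(1, nrow(m), by = 2L), seq(1, ncol(m), by = 2L), drop = FALSE]
}

resize_bilinear <- function(m, ny, nx) {
  sy <- nrow(m) / ny; sx <- ncol(m) / nx
  ys <- (seq_len(ny) - 0.5) * sy + 0.5
  xs <- (seq_len(nx) - 0.5) * sx + 0.5
  g <- bilinear_sample(m, matrix(rep(xs, each = ny), ny, nx),
                       matrix(rep(ys, times = nx), ny, nx))
  attr(g, "inbounds") <- NULL
  g
}

# neighbourhood average used by the Horn-Schunck update (weighted 8-neighbour
# Laplacian kernel, edge-replicated)
hs_avg <- function(m) {
  (shift_img(m, -1, 0) + shift_img(m, 1, 0) + shift_img(m, 0, -1) +
     shift_img(m, 0, 1)) / 6 +
  (shift_img(m, -1, -1) + shift_img(m, -1, 1) + shift_img(m, 1, -1) +
     shift_img(m, 1, 1)) / 12
}

central_diff_x <- function(m) (shift_img(m, 0, 1) - shift_img(m, 0, -1)) / 2
central_diff_y <- function(m) (shift_img(m, 1, 0) - shift_img(m, -1, 0)) / 2

#' Optical-flow parameters
#'
#' @param alpha smoothness regularisation weight (default 15).
#' @param iterations Jacobi iterations per warp (default 100).
#' @param levels pyramid depth; `NULL` selects
#'   `max(1, ceiling(log2(min(Ny, Nx) / 16)) + 1)`.
#' @param warps outer warp/linearisation iterations per level (default 3).
#' @param photometric compensate a global gain/bias between the warped frame
#'   and the reference at every warp iteration (default `TRUE`), so residual
#'   level or contrast mismatch is not mistaken for motion.
#' @return list of class `flow_params`.
#' @export
flow_params <- function(alpha = 15, iterations = 100L, levels = NULL,
                        warps = 3L, photometric = TRUE) {
  structure(list(alpha = alpha, iterations = as.integer(iterations),
                 levels = levels, warps = as.integer(warps),
                 photometric = isTRUE(photometric)),
            class = "flow_params")
}

#' Estimate the dense motion field between a frame and the reference
#'
#' Multi-scale Horn-Schunck global regularised optical flow. The returned
#' field satisfies `frame(x + du, y + dv) ~ ref(x, y)`: it is the
#' displacement to apply to reference coordinates to find each object in the
#' frame, i.e. exactly the field [warp_to_reference()] consumes.
#'
#' Both images should be level/range-adjusted single-channel images of the
#' same shape. A constant (texture-free) frame yields a zero field with a
#' `degenerate` attribute.
#'
#' @param frame,ref `gray_frame` objects (or plain matrices) of equal shape.
#' @param params a [flow_params()].
#' @return a [motion_field()].
#' @export
estimate_flow <- function(frame, ref, params = flow_params()) {
  Fm <- if (inherits(frame, "gray_frame")) frame$values else as.matrix(frame)
  Rm <- if (inherits(ref, "gray_frame")) ref$values else as.matrix(ref)
  if (!identical(dim(Fm), dim(Rm))) stop("frame and reference differ in shape")
  k_idx <- if (inherits(frame, "gray_frame")) frame$frame_index else 1L
  ny <- nrow(Fm); nx <- ncol(Fm)
  if (stats::sd(Fm) < 1e-12 || stats::sd(Rm) < 1e-12) {
    fld <- motion_field(matrix(0, ny, nx), matrix(0, ny, nx),
                        frame_index = k_idx)
    attr(fld, "degenerate") <- TRUE
    warning("degenerate (constant) image; returning zero motion field")
    return(fld)
  }
  n_levels <- params$levels
  if (is.null(n_levels))
    n_levels <- max(1L, as.integer(ceiling(log2(min(ny, nx) / 16))) + 1L)
  # contrast-normalise the pair to an 8-bit-like range so the smoothness
  # weight alpha is independent of the physical intensity scale
  lo <- min(Fm, Rm); hi <- max(Fm, Rm)
  sc <- 255 / (hi - lo)
  Fm <- (Fm - lo) * sc
  Rm <- (Rm - lo) * sc
  pyrF <- list(Fm); pyrR <- list(Rm)
  for (l in seq_len(n_levels - 1L)) {
    if (min(dim(pyrF[[l]])) < 8L) { n_levels <- l; break }
    pyrF[[l + 1L]] <- pyr_down(pyrF[[l]])
    pyrR[[l + 1L]] <- pyr_down(pyrR[[l]])
  }
  u <- matrix(0, nrow(pyrF[[n_levels]]), ncol(pyrF[[n_levels]]))
  v <- u
  a2 <- params$alpha^2
  for (l in seq(n_levels, 1L)) {
    Fl <- pyrF[[l]]; Rl <- pyrR[[l]]
    if (l < n_levels) {
      u <- resize_bilinear(u, nrow(Fl), ncol(Fl)) * 2
      v <- resize_bilinear(v, nrow(Fl), ncol(Fl)) * 2
    }
    xs0 <- matrix(rep(seq_len(ncol(Fl)), each = nrow(Fl)), nrow(Fl))
    ys0 <- matrix(rep(seq_len(nrow(Fl)), times = ncol(Fl)), nrow(Fl))
    for (w in seq_len(params$warps)) {
      Wl <- bilinear_sample(Fl, xs0 + u, ys0 + v)
      oob <- !attr(Wl, "inbounds"); attr(Wl, "inbounds") <- NULL
      if (params$photometric) {
        # global gain/bias compensation: residual level/contrast mismatch
        # between the frames (left over by the robust range adjustment)
        # must not masquerade as motion
        wi <- Wl[!oob]; ri <- Rl[!oob]
        vw <- stats::var(wi)
        if (is.finite(vw) && vw > 0) {
          gain <- stats::cov(wi, ri) / vw
          bias <- mean(ri) - gain * mean(wi)
          Wl <- gain * Wl + bias
        }
      }
      avg <- (Wl + Rl) / 2
      Ix <- central_diff_x(avg)
      Iy <- central_diff_y(avg)
      It <- Wl - Rl
      It[oob] <- 0
      # linearise about the current flow: data term Ix*u + Iy*v + c
      cc <- It - Ix * u - Iy * v
      den <- a2 + Ix^2 + Iy^2
      for (it in seq_len(params$iterations)) {
        ub <- hs_avg(u); vb <- hs_avg(v)
        num <- (Ix * ub + Iy * vb + cc) / den
        u <- ub - Ix * num
        v <- vb - Iy * num
      }
    }
  }
  motion_field(u, v, frame_index = k_idx)
}

#' Morph a frame back to the reference geometry
#'
#' Backward-samples the frame at its displaced coordinates with bilinear
#' interpolation: `out(x, y) = frame(x + du, y + dv)`. For a hyperspectral
#' cube the identical spatial field is applied to every wavelength channel.
#' Pixels whose sampling location falls outside the frame are marked invalid
#' (never extrapolated) — these are the black fringes around
#' motion-compensated frames.
#'
#' @param frame a `gray_frame`, plain matrix, or `hyper_cube`.
#' @param field a [motion_field()] matching the frame's spatial shape.
#' @return same type as `frame` with an updated validity mask.
#' @export
warp_to_reference <- function(frame, field) {
  stopifnot(inherits(field, "motion_field"))
  co <- warp_coords(field)
  if (inherits(frame, "hyper_cube")) {
    d <- cube_dim(frame)
    if (!identical(dim(field$du), d[1:2]))
      stop("motion field does not match the cube's spatial shape")
    out <- array(NA_real_, d)
    inb <- NULL
    for (j in seq_len(d[3L])) {
      s <- bilinear_sample(frame$values[, , j], co$xs, co$ys)
      if (is.null(inb)) inb <- attr(s, "inbounds")
      attr(s, "inbounds") <- NULL
      out[, , j] <- s
    }
    valid <- field$valid & inb
    # a warped pixel is valid only if its source neighbourhood was valid
    src_valid <- bilinear_sample(frame$valid * 1, co$xs, co$ys)
    valid <- valid & (src_valid >= 1 - 1e-12)
    out[!rep(valid, times = d[3L])] <- 0
    return(hyper_cube(out, frame$wavelengths, unit = frame$unit,
                      frame_index = frame$frame_index, valid = valid,
                      meta = frame$meta))
  }
  vals <- if (inherits(frame, "gray_frame")) frame$values else as.matrix(frame)
  if (!identical(dim(field$du), dim(vals)))
    stop("motion field does not match the frame's shape")
  s <- bilinear_sample(vals, co$xs, co$ys)
  inb <- attr(s, "inbounds"); attr(s, "inbounds") <- NULL
  valid <- field$valid & inb
  if (inherits(frame, "gray_frame")) {
    src_valid <- bilinear_sample(frame$valid * 1, co$xs, co$ys)
    valid <- valid & (src_valid >= 1 - 1e-12)
    s[!valid] <- NA_real_
    return(gray_frame(s, valid, frame$frame_index))
  }
  attr(s, "valid") <- valid
  s
}

#' Downstream validity mask of a motion field
#'
#' Pixels are excluded when their displacement magnitude exceeds `max_disp`
#' or when back-morphing sampled outside the frame. This mask gates all
#' pixel-wise processing after motion compensation.
#'
#' @param field a [motion_field()].
#' @param max_disp maximum tolerated displacement magnitude in pixels
#'   (default: 10\% of the smaller image side).
#' @return `Ny x Nx` logical matrix.
#' @export
validity_mask <- function(field, max_disp = NULL) {
  stopifnot(inherits(field, "motion_field"))
  if (is.null(max_disp)) max_disp <- 0.1 * min(dim(field$du))
  if (max_disp <= 0) stop("max_disp must be > 0")
  field$valid & (sqrt(field$du^2 + field$dv^2) <= max_disp)
}

#' Invert a dense displacement field
#'
#' Fixed-point iteration for the inverse field: given `d` mapping reference
#' coordinates to frame coordinates, finds `d_inv` with
#' `d_inv(xi) = -d(xi + d_inv(xi))`, so that sampling the reference-geometry
#' image at `xi + d_inv(xi)` renders the frame in its own geometry.
#'
#' @param field a [motion_field()].
#' @param iterations fixed-point iterations (default 10).
#' @return a [motion_field()] holding the inverse displacements.
#' @export
invert_field <- function(field, iterations = 10L) {
  co0 <- warp_coords(motion_field(field$du * 0, field$dv * 0))
  ui <- -field$du; vi <- -field$dv
  for (it in seq_len(iterations)) {
    du_s <- bilinear_sample(field$du, co0$xs + ui, co0$ys + vi)
    dv_s <- bilinear_sample(field$dv, co0$xs + ui, co0$ys + vi)
    attr(du_s, "inbounds") <- NULL; attr(dv_s, "inbounds") <- NULL
    ui <- -du_s
    vi <- -dv_s
  }
  motion_field(ui, vi, frame_index = field$frame_index)
}
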