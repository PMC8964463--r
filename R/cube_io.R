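#' @importFrom stats median rnorm runif sd cor
#' @importFrom utils modifyList
NULL

# ---------------------------------------------------------------------------
# Data model.
#
# A hyperspectral video is a time-ordered sequence of frames. Each frame is a
# cube of Ny x Nx pixels by J wavelength channels; values[y, x, j] holds the
# signal of the pixel in image row y (vertical, 1-based, top to bottom) and
# column x (horizontal, 1-based, left to right) at the j-th channel. The unit
# tag tracks the calibration state; transitions happen only through
# to_reflectance() / to_absorbance().
# ---------------------------------------------------------------------------

CUBE_UNITS <- c("intensity", "reflectance", "absorbance")

#' Construct a hyperspectral frame
#'
#' A `hyper_cube` holds one frame of a hyperspectral video: an
#' `Ny x Nx x J` array of per-pixel spectra plus its wavelength axis and a
#' unit tag (`intensity`, `reflectance` or `absorbance`). An optional
#' `Ny x Nx` logical validity mask marks pixels whose values are meaningful;
#' all statistics downstream are computed over valid pixels only.
#'
#' @param values numeric array of dimension `c(Ny, Nx, J)` (rows are the
#'   vertical image coordinate y, columns the horizontal coordinate x).
#' @param wavelengths strictly increasing numeric vector of length `J`, in nm.
#' @param unit one of `"intensity"`, `"reflectance"`, `"absorbance"`.
#' @param frame_index integer position of the frame in its video (>= 1).
#' @param valid optional `Ny x Nx` logical mask; `NULL` means all valid.
#' @param meta named list of free-form metadata (e.g. sample weight in g).
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths, unit = "intensity",
                       frame_index = 1L, valid = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-way array (Ny x Nx x J)")
  unit <- match.arg(unit, CUBE_UNITS)
  d <- dim(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != d[3L])
    stop(sprintf("wavelength axis has length %d but cube has %d channels",
                 length(wavelengths), d[3L]))
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(valid)) {
    valid <- matrix(TRUE, d[1L], d[2L])
  } else {
    valid <- as.matrix(valid)
    if (!identical(dim(valid), d[1:2]))
      stop("validity mask dimensions do not match the cube's spatial grid")
    storage.mode(valid) <- "logical"
  }
  if (any(!is.finite(values[rep(valid, times = d[3L])])))
    stop("non-finite values found on valid pixels")
  structure(list(values = values, wavelengths = wavelengths, unit = unit,
                 frame_index = as.integer(frame_index), valid = valid,
                 meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d channels (%.0f-%.0f nm), unit=%s, frame %d\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              x$unit, x$frame_index))
  invisible(x)
}

cube_dim <- function(cube) dim(cube$values)

#' Pair a dark and a white reference cube
#'
#' The calibration pair holds the dark-current and white-standard
#' (e.g. Spectralon) intensity cubes used to convert raw camera counts to
#' reflectance. For line-scan cameras a single-line reference (`Ny = 1`) is
#' accepted and broadcast across image rows at calibration time.
#'
#' @param dark,white `hyper_cube` objects with `unit = "intensity"`, equal
#'   shapes and identical wavelength axes.
#' @param tol entries where `white <= dark + tol` are counted as offenders;
#'   more than 1\% of offending entries is an error.
#' @return an object of class `calibration_pair`.
#' @export
calibration_pair <- function(dark, white, tol = 0) {
  stopifnot(inherits(dark, "hyper_cube"), inherits(white, "hyper_cube"))
  if (dark$unit != "intensity" || white$unit != "intensity")
    stop("calibration references must be in intensity units")
  if (!identical(dim(dark$values), dim(white$values)))
    stop("dark and white references differ in shape")
  if (!isTRUE(all.equal(dark$wavelengths, white$wavelengths)))
    stop("dark and white references differ in wavelength axis")
  bad <- white$values <= dark$values + tol
  n_bad <- sum(bad)
  if (n_bad > 0.01 * length(bad))
    stop(sprintf("white <= dark on %d of %d entries (> 1%%); unusable references",
                 n_bad, length(bad)))
  if (n_bad > 0)
    warning(sprintf("white <= dark on %d entries; affected pixels will be flagged invalid",
                    n_bad))
  structure(list(dark = dark, white = white), class = "calibration_pair")
}

#' Construct a hyperspectral video
#'
#' @param frames list of `hyper_cube` objects sharing shape, unit and
#'   wavelength axis; re-indexed 1..K in the given order.
#' @param timestamps optional length-K numeric vector (time stamps or an
#'   auxiliary per-frame covariate such as sample weight in g).
#' @return an object of class `video_sequence`.
#' @export
video_sequence <- function(frames, timestamps = NULL) {
  if (length(frames) < 1L) stop("a video needs at least one frame")
  d1 <- dim(frames[[1L]]$values)
  wl <- frames[[1L]]$wavelengths
  u <- frames[[1L]]$unit
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "hyper_cube")) stop("all frames must be hyper_cube objects")
    if (!identical(dim(f$values), d1))
      stop(sprintf("frame %d has shape (%s); expected (%s)", k,
                   paste(dim(f$values), collapse = "x"),
                   paste(d1, collapse = "x")))
    if (!isTRUE(all.equal(f$wavelengths, wl)))
      stop(sprintf("frame %d has a mismatched wavelength axis", k))
    if (f$unit != u) stop(sprintf("frame %d has unit '%s'; expected '%s'",
                                  k, f$unit, u))
    frames[[k]]$frame_index <- k
  }
  if (!is.null(timestamps) && length(timestamps) != length(frames))
    stop("timestamps length must equal the number of frames")
  structure(list(frames = frames, timestamps = timestamps), class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]]$values)
  cat(sprintf("<video_sequence> K=%d frames of %d x %d x %d (%s)\n",
              length(x$frames), d[1L], d[2L], d[3L], x$frames[[1L]]$unit))
  invisible(x)
}

n_frames <- function(video) length(video$frames)

# ---------------------------------------------------------------------------
# Radiometric calibration
# ---------------------------------------------------------------------------

broadcast_ref <- function(ref_values, ny) {
  if (dim(ref_values)[1L] == ny) return(ref_values)
  if (dim(ref_values)[1L] == 1L) {
    # line-scan convenience: replicate the single scanned line across rows
    d <- dim(ref_values)
    return(array(rep(ref_values, each = ny), dim = c(ny, d[2L], d[3L])))
  }
  stop("reference cube rows match neither the frame nor a single line")
}

#' Convert an intensity cube to reflectance
#'
#' Per pixel and channel, `R = (I - I_dark) / (I_white - I_dark)`. Pixels with
#' any channel where the white and dark references coincide are flagged
#' invalid rather than divided.
#'
#' @param cube a `hyper_cube` with `unit = "intensity"`.
#' @param cal a [calibration_pair()]; a single-line reference is broadcast
#'   across image rows.
#' @return a `hyper_cube` with `unit = "reflectance"`.
#' @export
to_reflectance <- function(cube, cal) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(cal, "calibration_pair"))
  if (cube$unit != "intensity")
    stop(sprintf("expected an intensity cube, got unit '%s'", cube$unit))
  d <- cube_dim(cube)
  dk <- broadcast_ref(cal$dark$values, d[1L])
  wt <- broadcast_ref(cal$white$values, d[1L])
  if (!identical(dim(dk), d))
    stop("calibration references do not match the cube's shape")
  if (!isTRUE(all.equal(cube$wavelengths, cal$dark$wavelengths)))
    stop("calibration references do not match the cube's wavelength axis")
  den <- wt - dk
  zero <- den == 0
  den[zero] <- 1
  R <- (cube$values - dk) / den
  valid <- cube$valid
  if (any(zero)) {
    R[zero] <- NA_real_
    valid <- valid & !apply(zero, c(1, 2), any)
  }
  hyper_cube(R, cube$wavelengths, unit = "reflectance",
             frame_index = cube$frame_index, valid = valid, meta = cube$meta)
}

#' Convert a reflectance cube to apparent absorbance
#'
#' `A = log10(1 / max(R, floor))`. The logarithm is undefined at `R <= 0`, so
#' reflectances are floored first; pixels with any floored channel are
#' recorded in `meta$floored_pixels`.
#'
#' @param cube a `hyper_cube` with `unit = "reflectance"`.
#' @param floor positive reflectance floor (default `1e-6`).
#' @return a `hyper_cube` with `unit = "absorbance"`.
#' @export
to_absorbance <- function(cube, floor = 1e-6) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (cube$unit != "reflectance")
    stop(sprintf("expected a reflectance cube, got unit '%s'", cube$unit))
  if (!is.numeric(floor) || floor <= 0) stop("`floor` must be > 0")
  R <- cube$values
  floored <- !is.na(R) & R < floor
  R[floored] <- floor
  A <- log10(1 / R)
  meta <- cube$meta
  meta$floored_pixels <- apply(floored, c(1, 2), any)
  meta$n_floored <- sum(floored)
  hyper_cube(A, cube$wavelengths, unit = "absorbance",
             frame_index = cube$frame_index, valid = cube$valid, meta = meta)
}

#' Calibrate a whole video to absorbance
#'
#' Convenience wrapper applying [to_reflectance()] then [to_absorbance()]
#' frame by frame.
#'
#' @inheritParams to_reflectance
#' @param video a `video_sequence` in intensity units.
#' @inheritParams to_absorbance
#' @return a `video_sequence` in absorbance units.
#' @export
calibrate_video <- function(video, cal, floor = 1e-6) {
  frames <- lapply(video$frames, function(f)
    to_absorbance(to_reflectance(f, cal), floor = floor))
  video_sequence(frames, video$timestamps)
}

# ---------------------------------------------------------------------------
# Unfold / refold
#
# Raster order: frames concatenated in time order; within a frame, pixels in
# R's column-major matrix order, i.e. y (image row) runs fastest, then x.
# ---------------------------------------------------------------------------

#' Unfold a video into a pixel-by-wavelength matrix
#'
#' Produces the `(Ny*Nx*K) x J` matrix in which each row is one pixel's
#' spectrum at one time point, together with an index map recovering
#' `(frame, y, x)` for every row. Row order is: frames in time order; within
#' a frame, column-major over the `Ny x Nx` image grid (y fastest, then x).
#'
#' @param video a `video_sequence` (or a single `hyper_cube`).
#' @return list with elements `X` (matrix), `index` (data.frame with columns
#'   `frame`, `y`, `x`), `dims` (`c(Ny, Nx, J, K)`), `wavelengths`, `unit`.
#' @export
unfold_video <- function(video) {
  if (inherits(video, "hyper_cube")) video <- video_sequence(list(video))
  stopifnot(inherits(video, "video_sequence"))
  d <- cube_dim(video$frames[[1L]])
  K <- n_frames(video)
  npx <- d[1L] * d[2L]
  X <- matrix(NA_real_, npx * K, d[3L])
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * npx + 1L):(k * npx)
    X[rows, ] <- matrix(video$frames[[k]]$values, npx, d[3L])
  }
  index <- data.frame(
    frame = rep(seq_len(K), each = npx),
    y = rep.int(rep(seq_len(d[1L]), times = d[2L]), K),
    x = rep.int(rep(seq_len(d[2L]), each = d[1L]), K))
  list(X = X, index = index, dims = c(d, K),
       wavelengths = video$frames[[1L]]$wavelengths,
       unit = video$frames[[1L]]$unit)
}

#' Refold an unfolded matrix back into a video
#'
#' Exact inverse of [unfold_video()]: `refold_video(unfold_video(v))`
#' reproduces `v`'s values bit-identically.
#'
#' @param unfolded list as returned by [unfold_video()] (the matrix `X` may
#'   have been replaced by an equally-shaped processed matrix).
#' @return a `video_sequence`.
#' @export
refold_video <- function(unfolded) {
  d <- unfolded$dims
  K <- d[4L]
  npx <- d[1L] * d[2L]
  if (nrow(unfolded$X) != npx * K)
    stop(sprintf("index map implies %d rows but matrix has %d",
                 npx * K, nrow(unfolded$X)))
  frames <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * npx + 1L):(k * npx)
    frames[[k]] <- hyper_cube(array(unfolded$X[rows, ], dim = d[1:3]),
                              unfolded$wavelengths, unit = unfolded$unit,
                              frame_index = k)
  }
  video_sequence(frames)
}

#' Dense storage footprint of a hyperspectral video
#'
#' Decimal gigabytes needed to hold an `Nx x Ny x K x J` video as
#' double-precision floats (8 bytes per value by default).
#'
#' @param nx,ny,k,j dataset dimensions (pixels, frames, channels).
#' @param bytes_per_value storage size of one value (default 8).
#' @return size in decimal GB (1 GB = 1e9 bytes).
#' @export
video_storage_gb <- function(nx, ny, k, j, bytes_per_value = 8) {
  as.numeric(nx) * ny * k * j * bytes_per_value / 1e9
}

# ---------------------------------------------------------------------------
# ENVI header + raster I/O (BIL / BIP / BSQ, little- or big-endian doubles
# and float32). Written with base R readBin/writeBin.
# ---------------------------------------------------------------------------

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path)) stop(sprintf("missing ENVI header '%s'", hdr_path))
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # key = value; a {...} value block may span lines
  pat <- gregexpr("(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  for (entry in regmatches(txt, pat)[[1L]]) {
    key <- trimws(sub("=.*$", "", entry))
    val <- trimws(sub("^[^=]*=", "", entry))
    fields[[tolower(key)]] <- gsub("\n", " ", val)
  }
  fields
}

envi_num <- function(fields, key, path) {
  v <- fields[[key]]
  if (is.null(v)) stop(sprintf("ENVI header '%s' lacks field '%s'", path, key))
  as.numeric(v)
}

#' Read one ENVI cube
#'
#' Reads an ENVI header/raster pair (`<stem>.hdr` + `<stem>.dat`, `.raw` or
#' `.img`) into a [hyper_cube()]. Supports BIL, BIP and BSQ interleaves, data
#' types 4 (float32) and 5 (float64), both byte orders.
#'
#' @param stem path without extension (or path to the `.hdr` file).
#' @param unit unit tag to apply (ENVI headers do not carry one); default
#'   `"intensity"`.
#' @param frame_index frame index to record.
#' @return a `hyper_cube`.
#' @export
read_envi_cube <- function(stem, unit = "intensity", frame_index = 1L) {
  stem <- sub("\\.hdr$", "", stem)
  hdr <- parse_envi_header(paste0(stem, ".hdr"))
  dat <- NULL
  for (ext in c(".dat", ".raw", ".img")) {
    if (file.exists(paste0(stem, ext))) { dat <- paste0(stem, ext); break }
  }
  if (is.null(dat)) stop(sprintf("no raster file found for '%s'", stem))
  nx <- envi_num(hdr, "samples", stem)
  ny <- envi_num(hdr, "lines", stem)
  nj <- envi_num(hdr, "bands", stem)
  dtype <- envi_num(hdr, "data type", stem)
  if (!dtype %in% c(4, 5))
    stop(sprintf("unsupported ENVI data type %d in '%s'", dtype, stem))
  interleave <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
  byte_order <- if (is.null(hdr[["byte order"]])) 0 else as.numeric(hdr[["byte order"]])
  endian <- if (byte_order == 0) "little" else "big"
  size <- if (dtype == 5) 8L else 4L
  n <- nx * ny * nj
  con <- file(dat, "rb"); on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = size, endian = endian)
  if (length(vals) != n)
    stop(sprintf("raster '%s' holds %d values; header implies %d", dat, length(vals), n))
  # ENVI stores samples (x) fastest within a line
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(nx, ny, nj)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(nx, nj, ny)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(nj, nx, ny)), c(3, 2, 1)),
    stop(sprintf("unknown interleave '%s' in '%s'", interleave, stem)))
  wl <- hdr$wavelength
  if (is.null(wl)) stop(sprintf("ENVI header '%s' lacks a wavelength block", stem))
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1L]])
  if (length(wl) != nj)
    stop(sprintf("ENVI header '%s': %d wavelengths for %d bands", stem, length(wl), nj))
  hyper_cube(arr, wl, unit = unit, frame_index = frame_index)
}

#' Write one ENVI cube
#'
#' @param cube a `hyper_cube`.
#' @param stem output path without extension; writes `<stem>.hdr` and
#'   `<stem>.dat`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @return `stem`, invisibly.
#' @export
write_envi_cube <- function(cube, stem, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  d <- cube_dim(cube)
  hdr <- c("ENVI",
           "description = {hypercine export}",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(stem, ".hdr"))
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1))))
  con <- file(paste0(stem, ".dat"), "wb"); on.exit(close(con))
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(stem)
}

#' Write a video as an ENVI directory of frames
#'
#' Each frame becomes `frame_####.hdr/.dat`; calibration references (if
#' supplied) become `dark.*` and `white.*`; `meta.json` records the unit,
#' timestamps and frame count.
#'
#' @param video a `video_sequence`.
#' @param dir output directory (created if needed).
#' @param cal optional [calibration_pair()].
#' @param interleave raster interleave, see [write_envi_cube()].
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir, cal = NULL, interleave = "bsq") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- n_frames(video)
  for (k in seq_len(K))
    write_envi_cube(video$frames[[k]],
                    file.path(dir, sprintf("frame_%04d", k)), interleave)
  if (!is.null(cal)) {
    write_envi_cube(cal$dark, file.path(dir, "dark"), interleave)
    write_envi_cube(cal$white, file.path(dir, "white"), interleave)
  }
  meta <- list(unit = video$frames[[1L]]$unit, n_frames = K,
               timestamps = video$timestamps)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a video from an ENVI directory of frames
#'
#' Inverse of [write_video()]. Frames are ordered by their file names; shape
#' or wavelength mismatches are reported naming the offending frame file.
#'
#' @param dir directory written by [write_video()] (or assembled by hand with
#'   the same layout).
#' @return list with `video` (a `video_sequence`) and `cal` (a
#'   `calibration_pair` or `NULL`).
#' @export
read_video <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory '%s'", dir))
  meta_path <- file.path(dir, "meta.json")
  unit <- "intensity"; timestamps <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$timestamps) && length(meta$timestamps)) timestamps <- meta$timestamps
  }
  stems <- sort(sub("\\.hdr$", "",
                    list.files(dir, pattern = "^frame_[0-9]+\\.hdr$",
                               full.names = TRUE)))
  if (!length(stems)) stop(sprintf("no frame_*.hdr files in '%s'", dir))
  frames <- vector("list", length(stems))
  for (k in seq_along(stems)) {
    frames[[k]] <- tryCatch(
      read_envi_cube(stems[k], unit = unit, frame_index = k),
      error = function(e) stop(sprintf("frame '%s': %s", basename(stems[k]),
                                       conditionMessage(e)), call. = FALSE))
    if (k > 1L) {
      if (!identical(dim(frames[[k]]$values), dim(frames[[1L]]$values)))
        stop(sprintf("frame '%s' has shape (%s); expected (%s)",
                     basename(stems[k]),
                     paste(dim(frames[[k]]$values), collapse = "x"),
                     paste(dim(frames[[1L]]$values), collapse = "x")))
      if (!isTRUE(all.equal(frames[[k]]$wavelengths, frames[[1L]]$wavelengths)))
        stop(sprintf("frame '%s' has a mismatched wavelength axis",
                     basename(stems[k])))
    }
  }
  video <- video_sequence(frames, timestamps)
  cal <- NULL
  if (file.exists(file.path(dir, "dark.hdr")) &&
      file.exists(file.path(dir, "white.hdr"))) {
    cal <- calibration_pair(read_envi_cube(file.path(dir, "dark")),
                            read_envi_cube(file.path(dir, "white")))
  }
  list(video = video, cal = cal)
}

#' Read a constituent spectrum from a two-column text table
#'
#' Reads a whitespace- or comma-delimited table of (wavelength nm, value)
#' rows, e.g. a dry-matter reference or pure-water absorptivity profile. The
#' table's wavelengths must match the target axis exactly (no resampling is
#' performed; a mismatch is an error).
#'
#' @param path text file; lines starting with `#` are ignored.
#' @param wavelengths target wavelength axis the spectrum must match.
#' @param tol wavelength matching tolerance in nm (default `1e-6`).
#' @return numeric vector of length `length(wavelengths)`.
#' @export
read_constituent_spectrum <- function(path, wavelengths, tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("'%s' line %d is not a two-column record", path, bad[1L]))
  tab <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(tab))) stop(sprintf("non-numeric entries in '%s'", path))
  idx <- match_wavelengths(tab[, 1L], wavelengths, tol)
  tab[idx, 2L]
}

match_wavelengths <- function(have, want, tol = 1e-6) {
  idx <- vapply(want, function(w) {
    hit <- which(abs(have - w) <= tol)
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1L))
  if (anyNA(idx)) {
    miss <- want[is.na(idx)]
    stop(sprintf("no exact wavelength match for %s nm (resampling is not supported)",
                 paste(format(miss[seq_len(min(3, length(miss)))]), collapse = ", ")))
  }
  idx
}
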