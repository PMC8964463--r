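# Shared fixtures, all generated in code.

# band-limited analytic texture: sums of incommensurate sinusoids, so warped
# versions can be evaluated exactly at any continuous coordinate
tex_fun <- function(x, y) {
  0.5 * sin(0.21 * x + 0.13 * y) + 0.4 * cos(0.17 * x - 0.09 * y) +
    0.3 * sin(0.091 * x + 0.19 * y) + 0.25 * cos(0.11 * y + 0.05 * x)
}

tex_image <- function(ny, nx, dx = 0, dy = 0) {
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  tex_fun(xs - dx, ys - dy)
}

# small EMSC fixture: smooth reference + two constituent profiles
toy_spectra <- function(J = 80) {
  wl <- seq(930, 2200, length.out = J)
  list(wl = wl,
       r = exp(-((wl - 1400) / 300)^2) + 0.5 * exp(-((wl - 2000) / 200)^2),
       s_water = exp(-((wl - 1450) / 70)^2) + 1.3 * exp(-((wl - 1940) / 90)^2),
       s_other = exp(-((wl - 1150) / 120)^2))
}

toy_emsc_model <- function(J = 80, two = FALSE) {
  sp <- toy_spectra(J)
  cons <- if (two) list(water = sp$s_water, other = sp$s_other)
          else list(water = sp$s_water)
  emsc_model(sp$r, cons, wavelengths = sp$wl)
}

# random EMSC-generated spectra with known coefficients
random_emsc_spectra <- function(n, model, noise_sd = 0) {
  J <- length(model$reference)
  p <- length(model$coef_names)
  coefs <- cbind(b = runif(n, 0.5, 2),
                 matrix(runif(n * (p - 4L), -0.5, 0.5), n,
                        dimnames = list(NULL, model$coef_names[2:(p - 3L)])),
                 a = runif(n, -0.3, 0.3), d = runif(n, -0.2, 0.2),
                 g = runif(n, -0.1, 0.1))
  colnames(coefs) <- model$coef_names
  X <- coefs %*% t(model$design_orig)
  if (noise_sd > 0) X <- X + matrix(rnorm(n * J, 0, noise_sd), n)
  list(X = X, coefs = coefs)
}

# tiny intensity video + calibration pair built by hand
toy_video <- function(ny = 8, nx = 8, J = 5, K = 3, seed = 11) {
  set.seed(seed)
  wl <- seq(1000, 2000, length.out = J)
  dark <- hyper_cube(array(100, c(ny, nx, J)), wl)
  white <- hyper_cube(array(1100 + rep(seq_len(J), each = ny * nx), c(ny, nx, J)), wl)
  frames <- lapply(seq_len(K), function(k)
    hyper_cube(array(runif(ny * nx * J, 200, 1000), c(ny, nx, J)), wl,
               frame_index = k))
  list(video = video_sequence(frames),
       cal = calibration_pair(dark, white), wl = wl)
}

small_synth <- function(seed = 7, ...) {
  synth_generate(synth_config(nx = 32, ny = 24, J = 30, K = 6, seed = seed, ...))
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
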