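test_that("fitting the reference returns identity coefficients", {
  m <- toy_emsc_model()
  fit <- emsc_fit(m$reference, m)
  expect_all_equal(fit$coefficients,
                   cbind(b = 1, h_water = 0, a = 0, d = 0, g = 0), tol = 1e-10)
  expect_all_equal(fit$residuals, 0, tol = 1e-10)
})

test_that("noise-free constructed spectra are recovered exactly", {
  m <- toy_emsc_model(two = TRUE)
  f <- m$f
  x <- 1.7 * m$reference + 0.4 * m$constituents[, "water"] -
    0.15 * m$constituents[, "other"] + 0.2 - 0.05 * f + 0.02 * f^2
  fit <- emsc_fit(x, m)
  expect_all_equal(fit$coefficients,
                   cbind(b = 1.7, h_water = 0.4, h_other = -0.15,
                         a = 0.2, d = -0.05, g = 0.02), tol = 1e-8)
  # reconstruction identity to machine precision
  expect_all_equal(fit$coefficients %*% t(m$design_orig) + fit$residuals,
                   matrix(x, 1), tol = 1e-12)
  # full correction inverts the model exactly
  expect_all_equal(emsc_correct_full(x, fit, m), matrix(m$reference, 1),
                   tol = 1e-8)
})

test_that("batch recovery holds over many random noise-free spectra", {
  set.seed(101)
  m <- toy_emsc_model(two = TRUE)
  gen <- random_emsc_spectra(200, m)
  fit <- emsc_fit(gen$X, m)
  rel <- abs(fit$coefficients - gen$coefs) / pmax(abs(gen$coefs), 1e-6)
  expect_lt(max(rel), 1e-8)
  corrected <- emsc_correct_full(gen$X, fit, m)
  expect_lt(max(abs(sweep(corrected, 2L, m$reference, "-"))), 1e-8)
})

test_that("residuals are weight-orthogonal to the design", {
  set.seed(5)
  m <- toy_emsc_model()
  x <- m$reference + rnorm(length(m$reference), 0, 0.05)
  fit <- emsc_fit(x, m)
  expect_all_equal(t(m$design_orig) %*% (m$weights * fit$residuals[1, ]), 0,
                   tol = 1e-10)
})

test_that("channel weights steer the fit as expected", {
  set.seed(6)
  sp <- toy_spectra(80)
  noisy_ch <- 30
  x <- 1.3 * sp$r + 0.2 * sp$s_water
  x[noisy_ch] <- x[noisy_ch] + 0.4      # corruption on one channel only
  m_id <- emsc_model(sp$r, list(water = sp$s_water), sp$wl)
  w <- rep(1, 80); w[noisy_ch] <- 0.01
  m_dn <- emsc_model(sp$r, list(water = sp$s_water), sp$wl, weights = w)
  f_id <- emsc_fit(x, m_id); f_dn <- emsc_fit(x, m_dn)
  truth <- c(1.3, 0.2)
  err_id <- abs(f_id$coefficients[1, c("b", "h_water")] - truth)
  err_dn <- abs(f_dn$coefficients[1, c("b", "h_water")] - truth)
  # down-weighting the corrupted channel moves coefficients toward truth...
  expect_true(all(err_dn <= err_id))
  # ...while the residual left on that channel grows
  expect_gt(abs(f_dn$residuals[1, noisy_ch]), abs(f_id$residuals[1, noisy_ch]))
})

test_that("scatter correction inverts multiplicative/baseline corruption", {
  set.seed(7)
  m <- toy_emsc_model()
  f <- m$f
  # identity coefficients leave the spectrum untouched
  x0 <- m$reference + 0.3 * m$constituents[, "water"]
  fit0 <- emsc_fit(x0, m)
  expect_all_equal(emsc_correct_scatter(2 * m$reference, emsc_fit(2 * m$reference, m), m),
                   matrix(m$reference, 1), tol = 1e-10)
  for (i in 1:20) {
    b <- runif(1, 0.3, 3); a <- runif(1, -0.5, 0.5)
    d <- runif(1, -0.3, 0.3); g <- runif(1, -0.2, 0.2)
    x <- b * m$reference + a + d * f + g * f^2
    fit <- emsc_fit(x, m)
    expect_all_equal(emsc_correct_scatter(x, fit, m), matrix(m$reference, 1),
                     tol = 1e-8)
  }
  # refitting a corrected spectrum yields identity coefficients, and the
  # abundance estimate survives the correction
  xc <- emsc_correct_scatter(x0 * 1.8 + 0.1, emsc_fit(x0 * 1.8 + 0.1, m), m)
  refit <- emsc_fit(xc[1, ], m)
  expect_all_equal(refit$coefficients[, c("b", "a", "d", "g")],
                   cbind(1, 0, 0, 0), tol = 1e-8)
  expect_equal(unname(refit$coefficients[, "h_water"]), 0.3, tolerance = 1e-8)
})

test_that("full correction equals scatter correction minus known chemistry", {
  set.seed(8)
  m <- toy_emsc_model(two = TRUE)
  gen <- random_emsc_spectra(20, m)
  fit <- emsc_fit(gen$X, m)
  sc <- emsc_correct_scatter(gen$X, fit, m)
  fu <- emsc_correct_full(gen$X, fit, m)
  b <- fit$coefficients[, "b"]
  H <- fit$coefficients[, c("h_water", "h_other")]
  expect_all_equal(fu, sc - (H / b) %*% t(m$constituents), tol = 1e-10)
})

test_that("residuals follow the projector and pathlength algebra", {
  m <- toy_emsc_model()
  J <- length(m$reference)
  x <- 1.4 * m$reference + 0.25 * m$constituents[, "water"]
  # noise-free model spectrum -> zero residual
  expect_all_equal(emsc_residual(x, emsc_fit(x, m), m), 0, tol = 1e-10)
  # a spike on one channel leaves exactly (I - P_M) * spike in the residual
  eps <- 0.3; ch <- 17
  x2 <- x; x2[ch] <- x2[ch] + eps
  fit2 <- emsc_fit(x2, m)
  M <- m$design_orig
  proj <- M %*% solve(crossprod(M), t(M))    # independent projector oracle
  spike <- rep(0, J); spike[ch] <- eps
  expect_all_equal(fit2$residuals[1, ], spike - proj %*% spike, tol = 1e-8)
  # pathlength-corrected residual is e / b
  x3 <- 2 * x2
  fit3 <- emsc_fit(x3, m)
  e <- emsc_residual(x3, fit3, m)
  et <- emsc_residual(x3, fit3, m, pathlength_corrected = TRUE)
  expect_all_equal(et, e / fit3$coefficients[1, "b"], tol = 1e-12)
  # and correct_full's own residual equals e / b
  fu <- emsc_correct_full(x3, fit3, m)
  expect_all_equal(fu - matrix(m$reference, 1), et, tol = 1e-8)
})

test_that("coefficients are scale-equivariant", {
  set.seed(9)
  m <- toy_emsc_model()
  x <- 1.2 * m$reference + 0.3 * m$constituents[, "water"] + 0.1 +
    rnorm(length(m$reference), 0, 0.02)
  f1 <- emsc_fit(x, m); f3 <- emsc_fit(3 * x, m)
  expect_all_equal(f3$coefficients, 3 * f1$coefficients, tol = 1e-9)
  expect_all_equal(f3$residuals, 3 * f1$residuals, tol = 1e-9)
})

test_that("collinear designs fail naming the offending columns", {
  sp <- toy_spectra(60)
  err <- tryCatch(emsc_model(sp$r, list(water = sp$r), sp$wl),
                  error = conditionMessage)
  expect_match(err, "rank deficient")
  expect_match(err, "h_water")
  expect_match(err, "'b'")
})

test_that("coefficient estimates are unbiased under i.i.d. noise", {
  set.seed(10)
  m <- toy_emsc_model()
  truth <- c(b = 1.5, h_water = 0.3, a = 0.1, d = -0.05, g = 0.02)
  x0 <- drop(m$design_orig %*% truth)
  n <- 400; sdn <- 0.01
  X <- matrix(x0, n, length(x0), byrow = TRUE) +
    matrix(rnorm(n * length(x0), 0, sdn), n)
  fit <- emsc_fit(X, m)
  bias <- colMeans(fit$coefficients) - truth
  se <- apply(fit$coefficients, 2, sd) / sqrt(n)
  expect_true(all(abs(bias) < 3 * se + 1e-12))
})

test_that("video-wise fits average pixel coefficients over valid pixels", {
  sp <- toy_spectra(40)
  wl <- sp$wl
  ny <- 4; nx <- 5; J <- 40
  m <- emsc_model(sp$r, list(water = sp$s_water), wl)
  # frame of pure reference everywhere -> b = 1, everything else 0
  const_frames <- lapply(1:3, function(k)
    hyper_cube(array(rep(sp$r, each = ny * nx), c(ny, nx, J)), wl,
               unit = "absorbance", frame_index = k))
  ef0 <- emsc_fit_video(video_sequence(const_frames), m)
  expect_all_equal(ef0$frame_coefficients[, "b"], 1, tol = 1e-10)
  expect_all_equal(ef0$frame_coefficients[, c("h_water", "a", "d", "g")], 0,
                   tol = 1e-10)
  # heterogeneous frame: reported trajectory is the mean of the pixel-wise
  # coefficients, not the fit of the mean spectrum
  set.seed(12)
  bmap <- matrix(runif(ny * nx, 0.5, 2), ny, nx)
  hmap <- matrix(runif(ny * nx, 0, 0.6), ny, nx)
  vals <- outer(as.vector(bmap), sp$r) + outer(as.vector(hmap), sp$s_water)
  fr <- hyper_cube(array(vals, c(ny, nx, J)), wl, unit = "absorbance")
  ef <- emsc_fit_video(video_sequence(list(fr)), m)
  expect_equal(unname(ef$frame_coefficients[1, "b"]), mean(bmap), tolerance = 1e-8)
  expect_equal(unname(ef$frame_coefficients[1, "h_water"]), mean(hmap),
               tolerance = 1e-8)
  alt <- emsc_fit_video(video_sequence(list(fr)), m, average = "mean_spectrum")
  mean_fit <- emsc_fit(colMeans(matrix(fr$values, ny * nx, J)), m)
  expect_equal(alt$frame_coefficients[1, ], mean_fit$coefficients[1, ])
  # maps carry the per-pixel values
  expect_all_equal(ef$maps[["b"]][, , 1], bmap, tol = 1e-8)
  # an all-masked frame yields a missing row, not zeros
  ef_masked <- emsc_fit_video(video_sequence(list(fr)), m,
                              masks = list(matrix(FALSE, ny, nx)))
  expect_true(all(is.na(ef_masked$frame_coefficients[1, ])))
  expect_equal(nrow(ef_masked$residual_frames[[1]]), 0L)
})

test_that("video fit recovers a declining abundance trajectory", {
  syn <- small_synth(seed = 21)
  m <- emsc_model(syn$truth$reference, list(water = syn$truth$water),
                  syn$truth$wavelengths)
  ab <- calibrate_video(syn$video, syn$cal)
  ef <- emsc_fit_video(ab, m)   # no motion compensation: coarse but monotone
  expect_gt(cor(ef$frame_coefficients[, "h_water"],
                syn$truth$abundance_trajectory), 0.95)
})
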