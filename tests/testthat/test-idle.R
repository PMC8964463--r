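test_that("flow of a frame against itself is zero", {
  img <- tex_image(48, 64)
  fld <- estimate_flow(img, img)
  expect_all_equal(fld$du, 0, tol = 1e-8)
  expect_all_equal(fld$dv, 0, tol = 1e-8)
  expect_true(all(fld$valid))
})

test_that("constant images yield a zero field with a degeneracy warning", {
  expect_warning(fld <- estimate_flow(matrix(1, 32, 32), matrix(1, 32, 32)),
                 "degenerate")
  expect_all_equal(fld$du, 0)
  expect_true(isTRUE(attr(fld, "degenerate")))
})

test_that("known translations and contractions are recovered", {
  ny <- 96; nx <- 128
  ref <- tex_image(ny, nx)
  inter <- function(m, b = 8) m[(b + 1):(ny - b), (b + 1):(nx - b)]
  # object moved +2 px in x: the field samples the frame at +2
  fld <- estimate_flow(tex_image(ny, nx, dx = 2), ref)
  expect_lt(abs(mean(inter(fld$du)) - 2), 0.2)
  expect_lt(abs(mean(inter(fld$dv))), 0.2)
  expect_lt(sqrt(mean(inter(fld$du - 2)^2 + inter(fld$dv)^2)), 0.3)
  # horizontal squeeze about the centre: x' = c + 0.95 (x - c)
  cx <- (nx + 1) / 2
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  frame <- tex_fun(cx + (xs - cx) / 0.95, ys)
  fld2 <- estimate_flow(frame, ref)
  true_du <- -0.05 * (xs - cx)
  expect_lt(sqrt(mean(inter(fld2$du - true_du)^2 + inter(fld2$dv)^2)), 0.3)
})

test_that("endpoint error decreases as noise vanishes", {
  set.seed(31)
  ny <- 64; nx <- 64
  ref <- tex_image(ny, nx)
  frame <- tex_image(ny, nx, dx = 1.5)
  inter <- function(m, b = 8) m[(b + 1):(ny - b), (b + 1):(nx - b)]
  rms <- vapply(c(0.2, 0.02, 0), function(sdn) {
    f <- frame + matrix(rnorm(ny * nx, 0, sdn), ny)
    r <- ref + matrix(rnorm(ny * nx, 0, sdn), ny)
    fld <- estimate_flow(f, r)
    sqrt(mean(inter(fld$du - 1.5)^2 + inter(fld$dv)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.3)
})

test_that("warping follows the backward-sampling contract", {
  img <- tex_image(40, 50)
  zero <- motion_field(matrix(0, 40, 50), matrix(0, 40, 50))
  # zero field is the identity with a full validity mask
  w0 <- warp_to_reference(gray_frame(img), zero)
  expect_identical(w0$values, img)
  expect_true(all(w0$valid))
  # integer shift is exact on valid pixels
  shift <- motion_field(matrix(3, 40, 50), matrix(-2, 40, 50))
  ws <- warp_to_reference(gray_frame(tex_image(40, 50, dx = 3, dy = -2)), shift)
  expect_all_equal(ws$values[ws$valid], img[ws$valid], tol = 1e-12)
  expect_false(all(ws$valid))          # border pixels sampled out of bounds
  # sub-pixel shift: linear interpolation error bounded by curvature/8
  sub <- motion_field(matrix(0.5, 40, 50), matrix(0, 40, 50))
  wsub <- warp_to_reference(gray_frame(tex_image(40, 50, dx = 0.5)), sub)
  err <- abs(wsub$values - img)[wsub$valid]
  curv_bound <- max(abs(diff(t(img), differences = 2))) / 8 * 1.5
  expect_lt(max(err), curv_bound)
})

test_that("warping a cube moves every channel by the same field", {
  set.seed(32)
  wl <- seq(1000, 1500, length.out = 4)
  vals <- array(0, c(30, 30, 4))
  for (j in 1:4) vals[, , j] <- tex_image(30, 30, dx = j)
  cube <- hyper_cube(vals, wl, unit = "absorbance")
  fld <- motion_field(matrix(1, 30, 30), matrix(0, 30, 30))
  wc <- warp_to_reference(cube, fld)
  for (j in 1:4)
    expect_all_equal(wc$values[, , j][wc$valid], tex_image(30, 30, dx = j - 1)[wc$valid],
                     tol = 1e-12)
  # warp commutes with band averaging for channel-uniform fields
  g_then_warp <- warp_to_reference(to_grayscale(cube, c(1, 3)), fld)
  warp_then_g <- to_grayscale(wc, c(1, 3))
  expect_all_equal(g_then_warp$values[g_then_warp$valid],
                   warp_then_g$values[g_then_warp$valid], tol = 1e-12)
})

test_that("validity masking matches a brute-force displacement check", {
  set.seed(33)
  du <- matrix(rnorm(20 * 25, sd = 2), 20, 25)
  dv <- matrix(rnorm(20 * 25, sd = 2), 20, 25)
  fld <- motion_field(du, dv)
  zero <- motion_field(matrix(0, 20, 25), matrix(0, 20, 25))
  expect_true(all(validity_mask(zero, 1)))
  m <- validity_mask(fld, 3)
  brute <- fld$valid & (sqrt(du^2 + dv^2) <= 3)
  expect_identical(m, brute)
  expect_equal(sum(!m), sum(!brute))
  # a single offending pixel is excluded exactly
  du1 <- matrix(0, 20, 25); du1[7, 9] <- 4
  m1 <- validity_mask(motion_field(du1, matrix(0, 20, 25)), 3)
  expect_false(m1[7, 9])
  expect_equal(sum(!m1), 1L)
  expect_error(validity_mask(fld, 0), "max_disp")
})

test_that("bilinear models reproduce a truncated dense decomposition", {
  set.seed(34)
  # exact rank-1 matrix: one component, 100% explained, zero residual
  t1 <- rnorm(10); p1 <- rnorm(50)
  m1 <- fit_bilinear(outer(t1, p1), rank = 1)
  expect_equal(m1$explained_variance, 1)
  expect_all_equal(m1$scores %*% t(m1$loadings), outer(t1, p1), tol = 1e-10)
  # random matrix: truncation error equals the dense SVD oracle's
  X <- matrix(rnorm(10 * 50), 10, 50)
  for (A in c(2, 5)) {
    m <- fit_bilinear(X, rank = A)
    sv <- svd(X)
    oracle <- sv$u[, 1:A] %*% diag(sv$d[1:A]) %*% t(sv$v[, 1:A])
    expect_equal(sum((X - m$scores %*% t(m$loadings))^2),
                 sum((X - oracle)^2), tolerance = 1e-10)
    expect_equal(m$explained_variance, sv$d[1:A]^2 / sum(sv$d^2),
                 tolerance = 1e-12)
  }
  # orthonormal loadings, non-increasing explained variance
  m5 <- fit_bilinear(X, rank = 5)
  expect_all_equal(crossprod(m5$loadings), diag(5), tol = 1e-10)
  expect_true(all(diff(m5$explained_variance) <= 1e-12))
  # full decomposition explains everything
  mf <- fit_bilinear(X, rank = 10)
  expect_equal(sum(mf$explained_variance), 1, tolerance = 1e-10)
  # rank shrinks (with a warning) on rank-deficient input
  expect_warning(ms <- fit_bilinear(outer(t1, p1), rank = 3), "rank")
  expect_equal(ms$rank, 1L)
})

test_that("the reference frame scores at the origin of an uncentred motion fit", {
  set.seed(35)
  flds <- lapply(1:4, function(k) {
    s <- if (k == 4) 0 else 0.02 * k
    du <- s * (matrix(rep(1:20, each = 15), 15, 20) - 10.5)
    motion_field(du, matrix(0, 15, 20), frame_index = k)
  })
  M <- motion_matrix(flds)
  m <- fit_bilinear(M, rank = 2, center = FALSE)
  expect_all_equal(m$scores[4, ], 0, tol = 1e-10)
})

test_that("frames rebuilt from full-rank models match the originals", {
  ny <- 40; nx <- 50
  ref <- gray_frame(tex_image(ny, nx), frame_index = 3)
  # 3-frame toy video: two shifted frames plus the reference
  shifts <- list(c(1.2, 0), c(0, -0.8), c(0, 0))
  grays <- lapply(1:3, function(k)
    gray_frame(tex_image(ny, nx, dx = shifts[[k]][1], dy = shifts[[k]][2]), frame_index = k))
  flds <- lapply(1:3, function(k)
    motion_field(matrix(shifts[[k]][1], ny, nx), matrix(shifts[[k]][2], ny, nx),
                 frame_index = k))
  warped <- lapply(1:3, function(k) warp_to_reference(grays[[k]], flds[[k]]))
  mm <- fit_bilinear(motion_matrix(flds), rank = 2)
  dI <- t(vapply(1:3, function(k) {
    v <- warped[[k]]$values - ref$values
    v[!warped[[k]]$valid] <- 0
    as.vector(v)
  }, numeric(ny * nx)))
  im <- fit_bilinear(dI, rank = 2)
  # reference index reconstructs the reference exactly
  rec3 <- reconstruct_frame(3, mm, im, ref)
  expect_all_equal(rec3$values, ref$values, tol = 1e-10)
  # other frames match within interpolation error away from the border
  rec1 <- reconstruct_frame(1, mm, im, ref)
  ok <- rec1$valid
  ok[c(1:3, (ny - 2):ny), ] <- FALSE; ok[, c(1:3, (nx - 2):nx)] <- FALSE
  expect_lt(sqrt(mean((rec1$values - grays[[1]]$values)[ok]^2)), 0.02)
  # reconstruction error decreases with model rank (non-increasing up to
  # interpolation noise, since the projection property lives in model space
  # and the warp composition adds a small resampling error)
  errs <- vapply(0:2, function(A) {
    mmA <- fit_bilinear(motion_matrix(flds), rank = A)
    imA <- fit_bilinear(dI, rank = A)
    r <- reconstruct_frame(1, mmA, imA, ref)
    sqrt(mean((r$values - grays[[1]]$values)[ok & r$valid]^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-4))
  expect_lt(errs[3], errs[1] / 10)
})

test_that("field inversion undoes the forward displacement", {
  ny <- 40; nx <- 50
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  fld <- motion_field(0.04 * (xs - 25), matrix(0.3, ny, nx))
  inv <- invert_field(fld)
  # composing field and inverse returns (numerically) to the origin
  co <- list(xs = xs + fld$du)
  du_at <- hypercine:::bilinear_sample(inv$du, xs + fld$du,
                                       matrix(rep(seq_len(ny), nx), ny) + fld$dv)
  expect_lt(max(abs(fld$du + du_at)[5:35, 5:45]), 1e-6)
})

test_that("the squeeze phenotype appears as a monotone first motion score", {
  syn <- small_synth(seed = 41, vertical_jitter_sd = 0)
  m <- emsc_model(syn$truth$reference, list(water = syn$truth$water),
                  syn$truth$wavelengths)
  ab <- calibrate_video(syn$video, syn$cal)
  gs <- grayscale_sequence(ab, m)
  flds <- lapply(seq_len(6), function(k) {
    if (k == gs$ref_index)
      motion_field(matrix(0, 24, 32), matrix(0, 24, 32), frame_index = k)
    else estimate_flow(gs$grays[[k]], gs$reference)
  })
  mm <- fit_bilinear(motion_matrix(flds), rank = 2)
  s1 <- mm$scores[, 1]
  expect_true(all(diff(s1) < 0) || all(diff(s1) > 0))
})

test_that("flow on generator truth stays subpixel at high SNR", {
  # constant chemistry and no jitter: the only change between frames is the
  # geometric squeeze, the regime in which flow accuracy is interpretable
  syn <- small_synth(seed = 42, vertical_jitter_sd = 0, noise_sd = 1e-4,
                     water_start = 0.4, water_mid = 0.4, water_end = 0.4,
                     unknown_amp = 0)
  m <- emsc_model(syn$truth$reference, list(water = syn$truth$water),
                  syn$truth$wavelengths)
  ab <- calibrate_video(syn$video, syn$cal)
  gs <- grayscale_sequence(ab, m)
  obj <- syn$truth$object_mask
  for (k in c(1, 3)) {
    fld <- estimate_flow(gs$grays[[k]], gs$reference)
    tru <- syn$truth$displacement_fields[[k]]
    epe2 <- (fld$du - tru$du)^2 + (fld$dv - tru$dv)^2
    expect_lt(sqrt(mean(epe2[obj])), 0.3)
  }
})
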