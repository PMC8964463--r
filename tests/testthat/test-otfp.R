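orth_basis <- function(J, A, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(J * A), J, A)))
}

test_that("block projection is an exact orthogonal projector", {
  set.seed(51)
  J <- 30
  P <- orth_basis(J, 2, 51)
  ctr <- rnorm(J)
  m <- otfp_new(J)
  m$loadings <- P; m$center <- ctr; m$initialized <- TRUE
  # rows inside span(P) + center leave no residual
  Tg <- matrix(rnorm(20 * 2), 20)
  X_in <- matrix(ctr, 20, J, byrow = TRUE) + Tg %*% t(P)
  pr <- otfp_project_block(X_in, m)
  expect_all_equal(pr$residual, 0, tol = 1e-10)
  expect_all_equal(pr$scores, Tg, tol = 1e-10)
  # general block: residual orthogonal to the basis, Frobenius norm matches
  # the brute-force projector
  X <- matrix(rnorm(40 * J), 40)
  pr2 <- otfp_project_block(X, m)
  expect_all_equal(t(pr2$residual %*% P), 0, tol = 1e-10)
  Xc <- sweep(X, 2, ctr)
  brute <- Xc %*% (diag(J) - P %*% t(P))
  expect_equal(sqrt(sum(pr2$residual^2)), sqrt(sum(brute^2)), tolerance = 1e-10)
  # a rank-0 model returns the centred block
  m0 <- otfp_new(J)
  m0$center <- ctr; m0$initialized <- TRUE
  expect_all_equal(otfp_project_block(X, m0)$residual, Xc, tol = 1e-12)
  expect_error(otfp_project_block(X[, 1:5], m), "columns")
})

test_that("repeated data add no components; new directions are detected on arrival", {
  set.seed(52)
  J <- 40
  v1 <- c(1, rep(0, J - 1)); v2 <- c(0, 1, rep(0, J - 2))
  b1 <- outer(rnorm(120), v1)
  m <- otfp_new(J, refine_every = 100)
  m <- otfp_process_block(m, b1)
  expect_equal(ncol(m$loadings), 1L)
  m <- otfp_process_block(m, b1)           # identical block again
  expect_equal(ncol(m$loadings), 1L)
  expect_equal(m$blocks[[2]]$detected, 0L)
  # second direction appears only in block 3 and is detected there
  b3 <- outer(rnorm(120), v1) + outer(rnorm(120), v2)
  m <- otfp_process_block(m, b3)
  expect_equal(ncol(m$loadings), 2L)
  expect_equal(m$blocks[[3]]$detected, 1L)
  m <- otfp_process_block(m, b3)
  expect_equal(ncol(m$loadings), 2L)
  # loadings stay orthonormal and earlier scores were zero-padded
  expect_all_equal(crossprod(m$loadings), diag(2), tol = 1e-10)
  expect_equal(ncol(m$blocks[[1]]$scores), 2L)
  expect_all_equal(m$blocks[[1]]$scores[, 2], 0)
})

test_that("an extreme row is isolated instead of spawning a component", {
  set.seed(53)
  J <- 40
  v1 <- c(1, rep(0, J - 1))
  m <- otfp_new(J, refine_every = 100)
  m <- otfp_process_block(m, outer(rnorm(300), v1))
  expect_equal(ncol(m$loadings), 1L)
  blk <- outer(rnorm(300), v1)
  blk[40, ] <- blk[40, ] + 100 * rnorm(J)   # one wild row
  m <- otfp_process_block(m, blk)
  expect_equal(ncol(m$loadings), 1L)
  expect_equal(length(m$outliers), 1L)
  expect_equal(m$outliers[[1]]$rows, 40L)
})

test_that("refinement equals batch decomposition of everything seen", {
  set.seed(54)
  J <- 25
  P <- orth_basis(J, 3, 54)
  X <- matrix(rnorm(200 * 3), 200) %*% diag(c(4, 2, 1)) %*% t(P) +
    matrix(rnorm(200 * J, sd = 0.05), 200)
  # refine after a single block = batch PCA of that block
  m <- otfp_stream(X, block_size = 200, variance_target = 0.99)
  pc <- prcomp(X, center = TRUE)
  A <- ncol(m$loadings)
  expect_equal(A, 3L)
  for (a in seq_len(A))
    expect_lt(min(sum((m$loadings[, a] - pc$rotation[, a])^2),
                  sum((m$loadings[, a] + pc$rotation[, a])^2)), 1e-16)
  expect_all_equal(m$center, colMeans(X), tol = 1e-12)
})

test_that("streamed subspace matches the batch oracle on rank-3 data", {
  set.seed(55)
  J <- 60; N <- 4000
  P <- orth_basis(J, 3, 55)
  X <- cbind(rnorm(N, sd = 3), rnorm(N, sd = 2), rnorm(N, sd = 1)) %*% t(P) +
    matrix(rnorm(N * J, sd = 0.1), N)
  m <- otfp_stream(X, block_size = 400, variance_target = 0.99)
  expect_equal(ncol(m$loadings), 3L)
  sv <- svd(scale(X, scale = FALSE))
  ev_batch <- sum(sv$d[1:3]^2) / sum(sv$d^2)
  expect_lt(abs(otfp_explained_variance(m) - ev_batch) / ev_batch, 0.01)
  # principal angles against the generating subspace
  ang <- acos(pmin(svd(t(m$loadings) %*% P)$d, 1))
  expect_lt(max(ang), 5e-2)
})

test_that("subspace recovery holds across true ranks", {
  for (A_true in 1:4) {
    set.seed(560 + A_true)
    J <- 40; N <- 3000
    P <- orth_basis(J, A_true, 560 + A_true)
    scores <- matrix(rnorm(N * A_true), N) %*% diag(seq(3, 1, length.out = A_true), A_true)
    X <- scores %*% t(P) + matrix(rnorm(N * J, sd = 0.05), N)
    m <- otfp_stream(X, block_size = 500)
    expect_equal(ncol(m$loadings), A_true)
    ang <- acos(pmin(svd(t(m$loadings) %*% P)$d, 1))
    expect_lt(max(ang), 5e-2)
  }
})

test_that("explained variance on seen data never decreases", {
  set.seed(57)
  J <- 30
  P <- orth_basis(J, 2, 57)
  m <- otfp_new(J, refine_every = 3)
  evs <- numeric(0)
  for (g in 1:7) {
    X <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1)) %*% t(P) +
      matrix(rnorm(200 * J, sd = 0.05), 200)
    m <- otfp_process_block(m, X)
    evs <- c(evs, otfp_explained_variance(m))
  }
  m2 <- otfp_refine(m)
  expect_gte(otfp_explained_variance(m2) + 1e-9, otfp_explained_variance(m))
  expect_gte(ncol(m2$loadings), ncol(m$loadings))   # rank never shrinks
})

test_that("noiseless in-subspace streams reconstruct exactly", {
  set.seed(58)
  J <- 20
  P <- orth_basis(J, 2, 58)
  X <- matrix(rnorm(300 * 2), 300) %*% t(P)
  m <- otfp_stream(X, block_size = 100, final_refine = FALSE)
  expect_gte(otfp_explained_variance(m), 1 - 1e-10)
  for (g in 1:3) {
    rec <- otfp_reconstruct(m, g)
    expect_all_equal(rec, X[((g - 1) * 100 + 1):(g * 100), ], tol = 1e-8)
  }
  expect_error(otfp_reconstruct(m, 9), "block")
})

test_that("pure noise is compressed honestly, not explained away", {
  set.seed(59)
  X <- matrix(rnorm(4000 * 60, sd = 0.3), 4000)
  m <- otfp_stream(X, block_size = 500, variance_target = 0.95)
  expect_lte(ncol(m$loadings), 2L)
  expect_lt(otfp_explained_variance(m), 0.95)
  expect_true(m$target_unmet)
})

test_that("compression-ratio arithmetic matches the stored-scalar count", {
  set.seed(60)
  # stream shaped like a 20 x 20 spatial grid over 10 frames, 50 channels
  J <- 50; N <- 20 * 20 * 10
  P <- orth_basis(J, 2, 60)
  X <- matrix(rnorm(N * 2), N) %*% t(P) + matrix(rnorm(N * J, sd = 0.02), N)
  m <- otfp_stream(X, block_size = 500)
  A <- ncol(m$loadings)
  expect_equal(otfp_compression_ratio(m), (N * A + J * A + J) / (N * J))
})

test_that("identical streams give identical models", {
  set.seed(61)
  X <- matrix(rnorm(1000 * 30), 1000) %*% diag(c(rep(2, 3), rep(0.05, 27)))
  m1 <- otfp_stream(X, block_size = 250)
  m2 <- otfp_stream(X, block_size = 250)
  expect_identical(m1, m2)
  # sign convention: every loading's largest-magnitude element is positive
  for (a in seq_len(ncol(m1$loadings)))
    expect_gt(m1$loadings[which.max(abs(m1$loadings[, a])), a], 0)
})
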