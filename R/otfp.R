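# ---------------------------------------------------------------------------
# On-the-fly processing: a streaming, self-expanding bilinear subspace model
# of a row stream (here: pathlength-corrected EMSC residual spectra).
#
# The model keeps exact running sufficient statistics (observation count,
# column sum, raw second-moment matrix, J x J with J the channel count) plus
# the current centre, orthonormal loadings and per-block score rows. New
# blocks are projected onto the current subspace; directions whose residual
# variance clears a detection threshold are appended immediately; at regular
# intervals the whole basis is re-estimated from the sufficient statistics
# (equivalent to a batch eigendecomposition of everything seen so far).
# Rank never decreases: information about old observations is never lost.
# Everything is deterministic — no internal randomness, signs fixed so each
# loading's largest-magnitude element is positive.
# ---------------------------------------------------------------------------

#' Create an empty streaming subspace model
#'
#' @param J number of variables (spectral channels) per observation row.
#' @param variance_target fraction of total variance the refined basis aims
#'   to explain (default 0.99). Components are only added while they clear
#'   the noise floor, so on noise-dominated streams the target may honestly
#'   not be reached (the model then carries a `target_unmet` flag).
#' @param block_size default rows per block for [otfp_stream()] (4096).
#' @param refine_every refine the basis every this many blocks (16).
#' @param outlier_limit rows whose residual norm exceeds this multiple of the
#'   block's median residual norm are excluded from expansion (6); if more
#'   than 10\% of a block's rows exceed it they are treated as a new pattern,
#'   not outliers.
#' @param max_rank hard cap on the number of components (32).
#' @param min_component_variance absolute variance floor below which a
#'   candidate direction is treated as numerical noise (default 0). When the
#'   stream is the residual of an upstream model, set this relative to the
#'   parent data's scale so a numerically-perfect upstream fit does not seed
#'   spurious components from rounding error.
#' @return object of class `otfp_model`.
#' @export
otfp_new <- function(J, variance_target = 0.99, block_size = 4096L,
                     refine_every = 16L, outlier_limit = 6,
                     max_rank = 32L, min_component_variance = 0) {
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must lie in (0, 1]")
  structure(list(
    J = as.integer(J),
    loadings = matrix(0, J, 0L),
    center = rep(0, J),
    component_variance = numeric(0),
    noise_variance = 0,
    n_seen = 0L,
    sum_x = rep(0, J),
    moment = matrix(0, J, J),
    blocks = list(),          # per block: scores, n, resid_ss
    resid_ss = 0,
    blocks_since_refine = 0L,
    outliers = list(),
    initialized = FALSE,
    target_unmet = FALSE,
    config = list(variance_target = variance_target,
                  block_size = as.integer(block_size),
                  refine_every = as.integer(refine_every),
                  outlier_limit = outlier_limit,
                  max_rank = as.integer(max_rank),
                  min_component_variance = min_component_variance)),
    class = "otfp_model")
}

#' @export
print.otfp_model <- function(x, ...) {
  cat(sprintf("<otfp_model> J=%d, A=%d component(s), %d row(s) in %d block(s), EV %.2f%%\n",
              x$J, ncol(x$loadings), x$n_seen, length(x$blocks),
              100 * otfp_explained_variance(x)))
  invisible(x)
}

#' Current rank (number of components) of a streaming subspace model
#'
#' @param model an `otfp_model`.
#' @return integer component count.
#' @export
otfp_rank <- function(model) ncol(model$loadings)

# total variance per observation about the current centre, from exact stats
otfp_total_variance <- function(model) {
  if (model$n_seen == 0L) return(0)
  c_ <- model$center
  (sum(diag(model$moment)) - 2 * sum(c_ * model$sum_x) +
     model$n_seen * sum(c_^2)) / model$n_seen
}

#' Project a block onto the current subspace
#'
#' `T = (X - center) P`; `E = (X - center) - T P'` is orthogonal to the
#' span of the loadings. Does not change the model.
#'
#' @param X `N_g x J` matrix of observation rows.
#' @param model an `otfp_model`.
#' @return list with `scores` (`N_g x A`) and `residual` (`N_g x J`).
#' @export
otfp_project_block <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != model$J)
    stop(sprintf("block has %d columns; model expects %d", ncol(X), model$J))
  Xc <- sweep(X, 2L, model$center, "-")
  if (otfp_rank(model) == 0L)
    return(list(scores = matrix(0, nrow(X), 0L), residual = Xc))
  Tg <- Xc %*% model$loadings
  list(scores = Tg, residual = Xc - Tg %*% t(model$loadings))
}

# detection threshold for a candidate component's variance: it must stick
# out of the eigenvalue bulk of the residual (3x the median eigenvalue, a
# robust noise-level estimate) and exceed the variance-target floor
otfp_threshold <- function(model, lam) {
  max(3 * stats::median(lam),
      (1 - model$config$variance_target) * otfp_total_variance(model),
      model$config$min_component_variance)
}

#' Absorb one block into the model
#'
#' Updates the sufficient statistics, projects the block, flags outlier rows,
#' expands the subspace with any residual direction whose variance clears the
#' detection threshold `max(3 * noise_variance,
#' (1 - variance_target) * total_variance)`, stores the block's score rows
#' (earlier blocks are zero-padded on new components), and refines the basis
#' every `refine_every` blocks.
#'
#' @param model an `otfp_model`.
#' @param X `N_g x J` block of observation rows.
#' @return the updated model. The block's index is `length(model$blocks)`.
#' @export
otfp_process_block <- function(model, X) {
  X <- as.matrix(X)
  if (!nrow(X)) return(model)
  if (ncol(X) != model$J)
    stop(sprintf("block has %d columns; model expects %d", ncol(X), model$J))
  model$sum_x <- model$sum_x + colSums(X)
  model$moment <- model$moment + crossprod(X)
  model$n_seen <- model$n_seen + nrow(X)
  if (!model$initialized) {
    model$center <- model$sum_x / model$n_seen
    model$initialized <- TRUE
  }
  pr <- otfp_project_block(X, model)
  Tg <- pr$scores; E <- pr$residual
  # outlier isolation: extreme rows do not get to define new components,
  # unless they are so numerous that they clearly form a pattern
  rn <- sqrt(rowSums(E^2))
  scale_floor <- 1e-12 * sqrt(mean(rowSums(sweep(X, 2L, model$center, "-")^2)) + 1e-300)
  thr <- model$config$outlier_limit * max(stats::median(rn), scale_floor)
  out_rows <- which(rn > thr)
  if (length(out_rows) > 0.1 * nrow(X)) out_rows <- integer(0)
  keep <- setdiff(seq_len(nrow(E)), out_rows)
  # expansion: residual directions with variance above threshold
  added <- 0L
  if (length(keep) > 1L) {
    sv <- svd(E[keep, , drop = FALSE])
    lam <- sv$d^2 / length(keep)
    tau <- otfp_threshold(model, lam)
    # absolute floor: numerically-zero residuals (data already perfectly
    # modelled) must not seed components
    abs_floor <- 1e-12 * sum(diag(model$moment)) / model$n_seen
    n_new <- sum(lam > max(tau, abs_floor, 1e-12 * max(lam, 0)))
    n_new <- min(n_new, model$config$max_rank - otfp_rank(model))
    if (n_new > 0L) {
      V <- sv$v[, seq_len(n_new), drop = FALSE]
      # re-orthonormalise against the existing basis for numerical safety
      if (otfp_rank(model) > 0L)
        V <- V - model$loadings %*% (t(model$loadings) %*% V)
      qv <- qr(V)
      V <- qr.Q(qv)[, seq_len(qv$rank), drop = FALSE]
      fs <- fix_signs(matrix(0, 1L, ncol(V)), V)
      V <- fs$loadings
      model$loadings <- cbind(model$loadings, V)
      # zero-pad previously stored score rows on the new components
      model$blocks <- lapply(model$blocks, function(b) {
        b$scores <- cbind(b$scores, matrix(0, nrow(b$scores), ncol(V)))
        b
      })
      Tg <- cbind(Tg, sweep(X, 2L, model$center, "-") %*% V)
      E <- sweep(X, 2L, model$center, "-") - Tg %*% t(model$loadings)
      added <- ncol(V)
    }
  }
  if (otfp_rank(model) > model$config$max_rank)
    stop("rank cap exceeded")
  rss <- sum(E^2)
  model$resid_ss <- model$resid_ss + rss
  # running noise estimate from post-expansion residual energy
  model$noise_variance <- model$resid_ss / (model$n_seen * model$J)
  g <- length(model$blocks) + 1L
  model$blocks[[g]] <- list(scores = Tg, n = nrow(X), resid_ss = rss,
                            detected = added)
  if (length(out_rows))
    model$outliers[[length(model$outliers) + 1L]] <-
      list(block = g, rows = out_rows)
  model$component_variance <- if (otfp_rank(model))
    colSums(do.call(rbind, lapply(model$blocks, `[[`, "scores"))^2) / model$n_seen
  else numeric(0)
  model$blocks_since_refine <- model$blocks_since_refine + 1L
  if (model$blocks_since_refine >= model$config$refine_every)
    model <- otfp_refine(model)
  model
}

#' Refine the model from its sufficient statistics
#'
#' Re-estimates the centre and the loadings by an eigendecomposition of the
#' exact covariance of everything seen so far (equivalent to batch PCA of
#' the full stream). The rank is the smallest number of components reaching
#' the variance target, restricted to components above the noise floor, and
#' never smaller than the current rank. Stored score rows are mapped into
#' the new basis through the low-rank reconstruction of their blocks.
#'
#' @param model an `otfp_model` with at least one block seen.
#' @return the refined model.
#' @export
otfp_refine <- function(model) {
  if (model$n_seen == 0L) stop("no data seen yet")
  n <- model$n_seen
  mean_new <- model$sum_x / n
  C <- model$moment / n - tcrossprod(mean_new)
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  tot <- sum(lam)
  A_old <- otfp_rank(model)
  if (tot <= 0) {
    A_new <- A_old
  } else {
    cum <- cumsum(lam) / tot
    A_target <- which(cum >= model$config$variance_target)[1L]
    if (is.na(A_target)) A_target <- length(lam)
    # components must stick out of the eigenvalue bulk to count
    noise_floor <- max(3 * stats::median(lam),
                       model$config$min_component_variance)
    A_floor <- sum(lam > pmax(noise_floor, 1e-12 * lam[1L]))
    A_new <- min(A_target, A_floor)
    model$target_unmet <- A_new < A_target
    A_new <- max(A_new, A_old)
    A_new <- min(A_new, model$config$max_rank, length(lam))
  }
  P_new <- eg$vectors[, seq_len(A_new), drop = FALSE]
  if (A_new > 0L) {
    fs <- fix_signs(matrix(0, 1L, A_new), P_new)
    P_new <- fs$loadings
  }
  # map stored scores: x_hat = center_old + t P_old'; t_new = (x_hat - center_new) P_new
  if (length(model$blocks)) {
    Rot <- if (A_old > 0L) t(model$loadings) %*% P_new else matrix(0, 0L, A_new)
    off <- drop(crossprod(P_new, model$center - mean_new))
    model$blocks <- lapply(model$blocks, function(b) {
      b$scores <- (if (A_old > 0L) b$scores %*% Rot
                   else matrix(0, b$n, A_new)) +
        matrix(off, b$n, A_new, byrow = TRUE)
      b
    })
  }
  model$loadings <- P_new
  model$center <- mean_new
  model$component_variance <- lam[seq_len(A_new)]
  model$resid_ss <- n * sum(lam[setdiff(seq_along(lam), seq_len(A_new))])
  model$noise_variance <- if (A_new < length(lam))
    sum(lam[setdiff(seq_along(lam), seq_len(A_new))]) / model$J
  else 0
  model$blocks_since_refine <- 0L
  model
}

#' Reconstruct a stored block
#'
#' @param model an `otfp_model`.
#' @param block_index index of a processed block.
#' @return `N_g x J` matrix `center + T_g P'`.
#' @export
otfp_reconstruct <- function(model, block_index) {
  if (block_index < 1L || block_index > length(model$blocks))
    stop(sprintf("unknown block index %s", block_index))
  b <- model$blocks[[block_index]]
  matrix(model$center, b$n, model$J, byrow = TRUE) +
    (if (otfp_rank(model) > 0L) b$scores %*% t(model$loadings) else 0)
}

#' Global explained variance of the stream
#'
#' `1 - sum ||E||^2 / sum ||X - center||^2` over everything seen, evaluated
#' exactly from the sufficient statistics and the current basis.
#'
#' @param model an `otfp_model`.
#' @return fraction in `[0, 1]`.
#' @export
otfp_explained_variance <- function(model) {
  if (model$n_seen == 0L) return(0)
  tv <- otfp_total_variance(model)
  if (tv <= 0) return(1)
  if (otfp_rank(model) == 0L) return(0)
  # explained variance = trace(P' C_c P) / trace(C_c), C_c about current centre
  c_ <- model$center
  n <- model$n_seen
  Cc <- model$moment / n - tcrossprod(c_, model$sum_x / n) -
    tcrossprod(model$sum_x / n, c_) + tcrossprod(c_)
  sum(diag(t(model$loadings) %*% Cc %*% model$loadings)) / tv
}

#' Compression ratio of the model
#'
#' Stored scalars (score rows + loadings + centre) over raw scalars seen.
#'
#' @param model an `otfp_model`.
#' @return ratio in `(0, 1]`.
#' @export
otfp_compression_ratio <- function(model) {
  A <- otfp_rank(model)
  stored <- model$n_seen * A + model$J * A + model$J
  stored / (model$n_seen * model$J)
}

#' Stream a matrix through the model in blocks
#'
#' Splits the rows of `X` into consecutive blocks of `block_size` rows,
#' processes each, and optionally refines at the end.
#'
#' @param X row matrix to stream.
#' @param model an `otfp_model` (default: fresh model for `ncol(X)`).
#' @param block_size rows per block (default: the model's configured size).
#' @param final_refine refine from the sufficient statistics after the last
#'   block (default `TRUE`).
#' @param ... passed to [otfp_new()] when no model is supplied.
#' @return the updated model.
#' @export
otfp_stream <- function(X, model = NULL, block_size = NULL,
                        final_refine = TRUE, ...) {
  X <- as.matrix(X)
  if (is.null(model)) model <- otfp_new(ncol(X), ...)
  if (is.null(block_size)) block_size <- model$config$block_size
  starts <- seq(1L, nrow(X), by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, nrow(X))
    model <- otfp_process_block(model, X[s:e, , drop = FALSE])
  }
  if (final_refine) model <- otfp_refine(model)
  model
}
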