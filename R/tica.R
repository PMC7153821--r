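# Time-lagged independent component analysis: the linear projection whose
# components maximize autocorrelation at a chosen lag, ranking collective
# coordinates by slowness. The symmetrized estimator is used throughout, so
# eigenvalues are real and time-reversal leaves the model unchanged.

#' Estimate a tICA model from feature trajectories
#'
#' Builds instantaneous (C0) and time-lagged (Ct) covariance matrices from
#' all within-trajectory frame pairs (t, t + lag) — never across trajectory
#' boundaries — using the symmetric estimator: the mean and C0 average over
#' both pair members, and Ct is symmetrized as (Ct + Ct')/2. The generalized
#' eigenproblem `Ct v = lambda C0 v` is solved after adding a variance floor
#' to C0's diagonal (sin/cos features of rigid angles can be rank-deficient);
#' eigenvectors are C0-orthonormal, so projected components have unit
#' equilibrium variance.
#'
#' @param trajs list of `feature_trajectory` objects (or plain matrices).
#' @param lag lag time in frames (>= 0; lag 0 gives eigenvalues identically 1).
#' @param n_components number of slow components to retain (default 2,
#'   the tIC1/tIC2 pair used for landscapes).
#' @param regularization variance floor added to C0's diagonal (default 1e-10).
#' @return a `tica_model`: `lag`, `lag_ns`, `mean`, `eigenvalues` (descending,
#'   all computed), `components` (feature-dim x n_components), `n_components`,
#'   `regularization`.
#' @export
estimate_tica <- function(trajs, lag, n_components = 2, regularization = 1e-10) {
  if (inherits(trajs, "feature_trajectory") || is.matrix(trajs)) trajs <- list(trajs)
  mats <- lapply(trajs, function(x) if (inherits(x, "feature_trajectory")) x$features else as.matrix(x))
  frame_dt <- if (inherits(trajs[[1]], "feature_trajectory")) trajs[[1]]$frame_dt else 1
  lens <- vapply(mats, nrow, integer(1))
  if (lag < 0) stop("lag must be >= 0")
  if (any(lens <= lag)) {
    stop(sprintf("lag (%d frames) must be shorter than every trajectory; offending trajectory: %d (%d frames)",
                 lag, which(lens <= lag)[1], min(lens)))
  }
  d <- ncol(mats[[1]])
  X0 <- do.call(rbind, lapply(mats, function(m) m[seq_len(nrow(m) - lag), , drop = FALSE]))
  Xt <- do.call(rbind, lapply(mats, function(m) m[(1 + lag):nrow(m), , drop = FALSE]))
  N <- nrow(X0)
  if (2 * N < d) stop("too few frame pairs for the feature dimension")
  mu <- (colSums(X0) + colSums(Xt)) / (2 * N)
  X0c <- sweep(X0, 2, mu)
  Xtc <- sweep(Xt, 2, mu)
  C0 <- (crossprod(X0c) + crossprod(Xtc)) / (2 * N)
  Ct <- (crossprod(X0c, Xtc) + crossprod(Xtc, X0c)) / (2 * N)
  diag(C0) <- diag(C0) + regularization
  R <- tryCatch(chol(C0), error = function(e) {
    stop("singular C0 covariance; increase the regularization variance floor")
  })
  # whiten: M = R^-T Ct R^-1 is symmetric; eigenvectors map back via R^-1
  M <- backsolve(R, t(backsolve(R, Ct, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values > 1 + 1e-9 | e$values < -1 - 1e-9)) {
    warning("tICA eigenvalues outside [-1, 1]: finite-sampling noise or non-equilibrium data")
  }
  n_components <- min(n_components, d)
  V <- backsolve(R, e$vectors[, seq_len(n_components), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(lag = as.integer(lag), lag_ns = lag * frame_dt,
                 frame_dt = frame_dt, mean = mu,
                 eigenvalues = e$values, components = V,
                 n_components = n_components,
                 regularization = regularization),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model: lag %d frames (%.3g ns), %d components, leading eigenvalues %s>\n",
              x$lag, x$lag_ns, x$n_components,
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)), collapse = ", ")))
  invisible(x)
}

#' Project data into tIC space
#'
#' `y = components' (x - mean)`, applied identically to trajectory frames and
#' to featurized reference conformations.
#'
#' @param model a `tica_model`.
#' @param x a list of `feature_trajectory`/matrices (returns a `projection`),
#'   a single matrix (returns a coordinate matrix), or a feature vector
#'   (returns a k-vector).
#' @return projected coordinates; for trajectory lists, a `projection` with
#'   `coords` (frames x k) and `traj_lengths` segmentation.
#' @export
tica_project <- function(model, x) {
  proj_mat <- function(m) {
    m <- if (inherits(m, "feature_trajectory")) m$features else as.matrix(m)
    if (ncol(m) != length(model$mean)) {
      stop(sprintf("feature dimension %d does not match model dimension %d",
                   ncol(m), length(model$mean)))
    }
    sweep(m, 2, model$mean) %*% model$components
  }
  if (is.numeric(x) && is.null(dim(x))) {
    return(drop(proj_mat(matrix(x, nrow = 1))))
  }
  if (is.matrix(x) || inherits(x, "feature_trajectory")) {
    return(proj_mat(x))
  }
  coords <- lapply(x, proj_mat)
  structure(list(coords = do.call(rbind, coords),
                 traj_lengths = vapply(coords, nrow, integer(1)),
                 frame_dt = model$frame_dt),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection: %d frames in %d trajectories, %d tICs>\n",
              nrow(x$coords), length(x$traj_lengths), ncol(x$coords)))
  invisible(x)
}

# split a per-frame vector back into per-trajectory pieces
split_by_traj <- function(v, lengths) {
  f <- rep(seq_along(lengths), lengths)
  unname(split(v, f))
}
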