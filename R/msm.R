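# Markov-state model estimation: k-means microstates in tIC space, sliding
# transition counts, strong connectivity trimming, reversible maximum
# likelihood transition matrices, implied timescales, Chapman-Kolmogorov
# validation.

#' k-means discretization of tIC space into microstates
#'
#' k-means++ initialization with a fixed, recorded seed, followed by Lloyd
#' iterations until the relative inertia change falls below `tol` (or
#' `max_iter` iterations). Every frame is assigned to the nearest center
#' (Euclidean; ties to the lowest center index). A center emptied during
#' iteration is re-seeded from the point farthest from its current center.
#'
#' @param proj a `projection` (or plain coordinate matrix).
#' @param k number of microstates (default 150).
#' @param seed RNG seed for the k-means++ initialization (default 42,
#'   recorded in the output so runs are reproducible).
#' @param tol relative inertia convergence tolerance.
#' @param max_iter Lloyd iteration cap.
#' @return a `microstate_model`: `centers` (k x d), `dtrajs` (list of 1-based
#'   label vectors per trajectory), `labels` (flat), `k`, `seed`, `inertia`.
#' @export
kmeans_discretize <- function(proj, k = 150, seed = 42L, tol = 1e-6,
                              max_iter = 500L) {
  X <- if (inherits(proj, "projection")) proj$coords else as.matrix(proj)
  lengths <- if (inherits(proj, "projection")) proj$traj_lengths else nrow(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of frames")
  centers <- with_seed(seed, kmeanspp_init(X, k))
  fit <- .lloyd_iterate(X, centers, tol, as.integer(max_iter))
  centers <- fit$centers
  lab <- fit$labels
  inertia <- fit$inertia
  structure(list(centers = centers, labels = lab,
                 dtrajs = split_by_traj(lab, lengths),
                 k = as.integer(k), seed = as.integer(seed),
                 inertia = inertia),
            class = "microstate_model")
}

# squared Euclidean distances of all rows of X to all centers
assign_d2 <- function(X, centers, xs2 = rowSums(X^2)) {
  d2 <- -2 * tcrossprod(X, centers)
  d2 <- sweep(d2, 2, rowSums(centers^2), "+") + xs2
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  mind2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(mind2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = mind2)
    }
    centers[j + 1, ] <- X[pick, ]
    mind2 <- pmin(mind2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Count microstate transitions at a lag
#'
#' Sliding mode counts every pair (t, t + lag); strided mode counts pairs at
#' t = 1, 1 + lag, 1 + 2 lag, ... Pairs never cross trajectory boundaries;
#' trajectories not longer than the lag are excluded.
#'
#' @param dtrajs list of integer label vectors (1-based) or a single vector.
#' @param lag lag in frames (>= 1).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @param n_states number of states (default: maximum observed label).
#' @return a `count_matrix`: `counts` (n_states x n_states), `lag`, `mode`.
#' @export
count_transitions <- function(dtrajs, lag, mode = c("sliding", "strided"),
                              n_states = NULL) {
  mode <- match.arg(mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (lag < 1) stop("lag must be >= 1")
  usable <- dtrajs[vapply(dtrajs, length, integer(1)) > lag]
  if (length(usable) == 0) stop("all trajectories are shorter than the lag")
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, numeric(1)))
  C <- matrix(0, n_states, n_states)
  for (d in usable) {
    len <- length(d)
    from_t <- if (mode == "sliding") seq_len(len - lag) else seq(1, len - lag, by = lag)
    tab <- table(factor(d[from_t], levels = seq_len(n_states)),
                 factor(d[from_t + lag], levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  structure(list(counts = C, lag = as.integer(lag), mode = mode),
            class = "count_matrix")
}

#' Largest connected set of a count matrix
#'
#' Vertices of the largest strongly connected component of the directed graph
#' with an edge i -> j wherever counts[i, j] > 0. "Largest" maximizes the
#' total transition counts inside the component (ties: more states, then
#' lowest state index), because the retained-count fraction is what bounds
#' the information kept by trimming. Probabilities and relative equilibrium
#' weights are only meaningful on a fully connected network, so estimation is
#' restricted to this set.
#'
#' @param C a `count_matrix` or plain count matrix.
#' @return list: `active_set` (sorted state indices), `fraction_retained`
#'   (share of all counts with both endpoints in the set).
#' @export
largest_connected_set <- function(C) {
  counts <- if (inherits(C, "count_matrix")) C$counts else as.matrix(C)
  n <- nrow(counts)
  present <- which(rowSums(counts) + colSums(counts) > 0)
  if (length(present) == 0) {
    return(list(active_set = integer(0), fraction_retained = 0))
  }
  g <- igraph::graph_from_adjacency_matrix((counts[present, present, drop = FALSE] > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  total <- sum(counts)
  best <- NULL; best_score <- c(-1, -1, Inf)
  for (cm in seq_len(comp$no)) {
    members <- present[comp$membership == cm]
    w <- sum(counts[members, members])
    score <- c(w, length(members), -min(members))
    if (score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2]) ||
        (score[1] == best_score[1] && score[2] == best_score[2] && -score[3] < best_score[3])) {
      best <- members; best_score <- score
    }
  }
  list(active_set = sort(best),
       fraction_retained = if (total > 0) best_score[1] / total else 0)
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximum-likelihood estimate of a row-stochastic transition matrix under
#' detailed balance (pi_i T_ij = pi_j T_ji), via the standard fixed-point
#' iteration on symmetric count variables:
#' `x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)`,
#' iterated until the maximum relative change falls below `tol`. The
#' stationary distribution is read off the row sums of x.
#'
#' @param C a `count_matrix` (or matrix) — restricted internally to
#'   `active`, which defaults to the largest connected set.
#' @param tol convergence tolerance on the relative change of x (default 1e-12).
#' @param max_iter iteration cap (default 1e6).
#' @param frame_dt ns per frame, for the ns lag time (default 1).
#' @param active optional explicit active set (state indices).
#' @return an `ms_model`: `T` (row-stochastic on the active set),
#'   `stationary`, `lag` (frames), `lag_ns`, `active_set`,
#'   `fraction_retained`, `counts` (restricted).
#' @export
estimate_reversible_T <- function(C, tol = 1e-12, max_iter = 1e6,
                                  frame_dt = 1, active = NULL) {
  lag <- if (inherits(C, "count_matrix")) C$lag else 1L
  counts <- if (inherits(C, "count_matrix")) C$counts else as.matrix(C)
  if (is.null(active)) {
    lcs <- largest_connected_set(counts)
    active <- lcs$active_set
    fraction <- lcs$fraction_retained
  } else {
    fraction <- sum(counts[active, active]) / sum(counts)
  }
  if (length(active) == 0) stop("empty connected set; no transitions observed")
  Cs <- counts[active, active, drop = FALSE]
  n <- nrow(Cs)
  if (n == 1) {
    T <- matrix(1, 1, 1); pi_ <- 1
  } else {
    g <- igraph::graph_from_adjacency_matrix((Cs > 0) * 1, mode = "directed")
    if (igraph::components(g, mode = "strong")$no != 1) {
      stop("count matrix restricted to 'active' is not strongly connected")
    }
    ci <- rowSums(Cs)
    Csym <- Cs + t(Cs)
    X <- Csym / sum(Csym)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      xi <- rowSums(X)
      denom <- outer(ci / xi, ci / xi, "+")
      Xnew <- Csym / denom
      Xnew[Csym == 0] <- 0
      Xnew <- Xnew / sum(Xnew)
      delta <- max(abs(Xnew - X) / pmax(X, 1e-300))
      X <- Xnew
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("reversible estimator did not converge (last residual %.3g)", delta))
    }
    xi <- rowSums(X)
    T <- X / xi
    pi_ <- xi / sum(xi)
  }
  model <- structure(list(T = T, stationary = pi_, lag = as.integer(lag),
                          lag_ns = lag * frame_dt, frame_dt = frame_dt,
                          active_set = active, fraction_retained = fraction,
                          counts = Cs),
                     class = "ms_model")
  validate_ms_model(model)
  model
}

validate_ms_model <- function(model, tol_row = 1e-10, tol_db = 1e-8) {
  T <- model$T; pi_ <- model$stationary
  stopifnot(max(abs(rowSums(T) - 1)) < tol_row,
            all(pi_ >= 0), abs(sum(pi_) - 1) < tol_row)
  db <- max(abs(pi_ * T - t(pi_ * T)))
  if (db > tol_db) stop(sprintf("detailed balance violated (residual %.3g)", db))
  invisible(model)
}

#' @export
print.ms_model <- function(x, ...) {
  cat(sprintf("<ms_model: %d states, lag %d frames (%.3g ns), %.1f%% of counts retained>\n",
              nrow(x$T), x$lag, x$lag_ns, 100 * x$fraction_retained))
  invisible(x)
}

# eigen-decomposition of a reversible T via pi-symmetrization:
# S = D^{1/2} T D^{-1/2} is symmetric, shares eigenvalues with T
reversible_spectrum <- function(T, pi_) {
  s <- sqrt(pi_)
  S <- (T * outer(s, 1 / s)) # D^{1/2} T D^{-1/2}
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  # right eigenvectors of T: psi = D^{-1/2} w
  psi <- e$vectors / s
  list(values = e$values, vectors = psi)
}

#' Implied relaxation timescales of a Markov-state model
#'
#' `t_i = -lag_ns / log(lambda_{i+1})` for the n largest nontrivial
#' eigenvalues. Eigenvalues at (or numerically above) 1 give infinite
#' timescales (disconnected kinetics) and are flagged; negative eigenvalues
#' have no timescale interpretation and are returned as NA with a warning.
#'
#' @param model an `ms_model`.
#' @param n number of timescales (default: all nontrivial).
#' @return numeric vector of timescales in ns.
#' @export
implied_timescales <- function(model, n = NULL) {
  k <- nrow(model$T)
  if (is.null(n)) n <- k - 1
  if (n >= k) stop("n must be smaller than the state count")
  if (n < 1) return(numeric(0))
  ev <- reversible_spectrum(model$T, model$stationary)$values
  lam <- ev[2:(n + 1)]
  ts <- rep(NA_real_, n)
  pos <- lam > 0 & lam < 1
  ts[pos] <- -model$lag_ns / log(lam[pos])
  ts[lam >= 1] <- Inf
  if (any(lam <= 0)) warning("negative eigenvalues: timescale undefined (NA)")
  ts
}

#' Implied timescales across several lags
#'
#' Convenience wrapper re-estimating the reversible model at each lag;
#' timescales of a Markovian process are flat in the lag.
#'
#' @param dtrajs list of discrete trajectories.
#' @param lags integer vector of lags in frames.
#' @param n number of timescales per lag.
#' @param frame_dt ns per frame.
#' @return data.frame with columns lag_frames, lag_ns, process, timescale_ns.
#' @export
implied_timescales_vs_lag <- function(dtrajs, lags, n = 3, frame_dt = 1) {
  do.call(rbind, lapply(lags, function(l) {
    m <- estimate_reversible_T(count_transitions(dtrajs, l), frame_dt = frame_dt)
    ts <- implied_timescales(m, min(n, nrow(m$T) - 1))
    data.frame(lag_frames = l, lag_ns = l * frame_dt,
               process = seq_along(ts), timescale_ns = ts)
  }))
}

#' Chapman-Kolmogorov test
#'
#' Compares, for each factor f, set-occupation transition probabilities
#' predicted by propagating the lag-tau model (`T^f`) against a model
#' re-estimated directly at lag f*tau. Probabilities are aggregated over
#' `macro_sets` (default: singleton microstates) with the lag-tau stationary
#' weights. A Markovian process shows near-zero deviations; memory shows up
#' as growing deviation with f.
#'
#' @param dtrajs discrete trajectories the model was estimated from.
#' @param model the reference `ms_model` at lag tau.
#' @param factors integer lag multiples to test (default 2:5).
#' @param macro_sets optional list of microstate index sets (in original
#'   labels) defining the coarse sets; e.g. PCCA+ macrostates.
#' @return a `ck_result`: `factors`, `predicted` and `estimated` (lists of
#'   set-to-set matrices), `max_abs_deviation` per factor (factor 1 is 0 by
#'   construction and not tested).
#' @export
ck_test <- function(dtrajs, model, factors = 2:5, macro_sets = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  active <- model$active_set
  if (is.null(macro_sets)) macro_sets <- as.list(active)
  # membership of each active state in each set
  A <- vapply(macro_sets, function(s) as.numeric(active %in% s),
              numeric(length(active)))
  pi_ <- model$stationary
  pred <- list(); est <- list(); dev <- numeric(0); kept <- integer(0)
  for (f in sort(unique(as.integer(factors)))) {
    Tpow <- matpow(model$T, f)
    maxlen <- max(vapply(dtrajs, length, integer(1)))
    if (maxlen <= f * model$lag) {
      warning(sprintf("factor %d skipped: no trajectory longer than %d frames",
                      f, f * model$lag))
      next
    }
    mf <- estimate_reversible_T(count_transitions(dtrajs, f * model$lag,
                                                  n_states = max(active)),
                                frame_dt = model$frame_dt)
    common <- intersect(active, mf$active_set)
    ia <- match(common, active); ib <- match(common, mf$active_set)
    Ac <- A[ia, , drop = FALSE]
    wc <- pi_[ia]
    spp <- function(T) {
      num <- t(Ac * wc) %*% T %*% Ac
      num / rowSums(t(Ac * wc))
    }
    P <- spp(Tpow[ia, ia, drop = FALSE] / rowSums(Tpow[ia, ia, drop = FALSE]))
    E <- spp(mf$T[ib, ib, drop = FALSE] / rowSums(mf$T[ib, ib, drop = FALSE]))
    pred[[length(pred) + 1]] <- P
    est[[length(est) + 1]] <- E
    dev <- c(dev, max(abs(P - E)))
    kept <- c(kept, f)
  }
  structure(list(factors = kept, predicted = pred, estimated = est,
                 max_abs_deviation = dev),
            class = "ck_result")
}

matpow <- function(M, p) {
  R <- diag(nrow(M))
  B <- M
  while (p > 0) {
    if (p %% 2 == 1) R <- R %*% B
    B <- B %*% B
    p <- p %/% 2
  }
  R
}
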