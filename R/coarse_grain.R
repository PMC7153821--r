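# PCCA+ coarse-graining of the microstate MSM into metastable macrostates,
# macrostate statistics, and mean first passage times — the kinetic summary
# drawn on the landscape figures.

#' PCCA+ metastable coarse-graining
#'
#' Robust Perron cluster analysis on the reversible transition matrix: the
#' top `n_macro` right eigenvectors (pi-orthonormal, leading one constant)
#' span a simplex whose vertices are located by the inner-simplex
#' (Deuflhard-Weber) selection — iteratively picking the microstate row
#' farthest from the affine span of the vertices found so far. Fuzzy
#' memberships are the barycentric coordinates of each microstate row in
#' that simplex (clipped at zero and row-renormalized, since rows slightly
#' outside the simplex can occur for imperfectly metastable chains); no
#' membership-rotation optimization step is applied, keeping the result
#' deterministic.
#'
#' @param model an `ms_model` (reversible; real spectrum).
#' @param n_macro number of macrostates (>= 2, at most the number of
#'   positive eigenvalues).
#' @return a `macro_model`: `n_macro`, `chi` (k x n_macro memberships),
#'   `crisp` (per-microstate argmax macrostate, ties to the lowest index),
#'   `macro_pi` (stationary probability summed over members), `macro_sets`
#'   (member microstates in original labels), `mfpt_matrix` (ns, between
#'   crisp macrostates), `active_set`.
#' @export
pcca_plus <- function(model, n_macro) {
  k <- nrow(model$T)
  if (n_macro < 2) stop("n_macro must be >= 2")
  spec <- reversible_spectrum(model$T, model$stationary)
  if (sum(spec$values > 0) < n_macro) {
    stop("not enough positive eigenvalues for the requested macrostate count; estimate reversibly or lower n_macro")
  }
  Psi <- spec$vectors[, seq_len(n_macro), drop = FALSE]
  # normalize the trivial eigenvector to exactly 1 (it is constant up to sign)
  Psi[, 1] <- 1
  verts <- inner_simplex_vertices(Psi)
  chi <- Psi %*% solve(Psi[verts, , drop = FALSE])
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  # order macrostates by decreasing stationary weight for stable reporting
  macro_pi_raw <- vapply(seq_len(n_macro), function(m) sum(model$stationary[crisp == m]),
                         numeric(1))
  ord <- order(macro_pi_raw, decreasing = TRUE)
  chi <- chi[, ord, drop = FALSE]
  crisp <- match(crisp, ord)
  macro_pi <- macro_pi_raw[ord]
  macro_sets <- lapply(seq_len(n_macro), function(m) model$active_set[crisp == m])
  M <- mfpt_matrix_sets(model, macro_sets)
  structure(list(n_macro = as.integer(n_macro), chi = chi, crisp = crisp,
                 macro_pi = macro_pi, macro_sets = macro_sets,
                 mfpt_matrix = M, active_set = model$active_set),
            class = "macro_model")
}

# Deuflhard-Weber vertex search: first vertex = row of largest norm after
# centering; each next vertex = row farthest from the span of previous ones.
inner_simplex_vertices <- function(Psi) {
  m <- ncol(Psi)
  C <- Psi
  verts <- integer(m)
  v <- which.max(rowSums(C^2))
  verts[1] <- v
  C <- sweep(C, 2, C[v, ])
  for (j in 2:m) {
    v <- which.max(rowSums(C^2))
    verts[j] <- v
    dir <- C[v, ] / sqrt(sum(C[v, ]^2))
    C <- C - outer(drop(C %*% dir), dir)
  }
  verts
}

#' @export
print.macro_model <- function(x, ...) {
  cat(sprintf("<macro_model: %d macrostates, probabilities %s>\n", x$n_macro,
              paste(sprintf("%.3f", x$macro_pi), collapse = ", ")))
  invisible(x)
}

#' Mean first passage time between microstate sets
#'
#' Solves the first-passage linear system `m_i = tau + sum_{j not in target}
#' T_ij m_j` with `m = 0` on the target; the reported value is the
#' stationary-weighted average of `m` over the source set, in ns.
#'
#' @param model an `ms_model`.
#' @param source,target disjoint, non-empty microstate sets (original labels).
#' @return MFPT in ns; `Inf` if the target is unreachable from the source.
#' @export
mfpt <- function(model, source, target) {
  act <- model$active_set
  src <- match(source, act); tgt <- match(target, act)
  if (anyNA(src) || anyNA(tgt)) stop("source/target must lie in the active set")
  if (length(intersect(src, tgt)) > 0) stop("source and target must be disjoint")
  k <- nrow(model$T)
  free <- setdiff(seq_len(k), tgt)
  Tff <- model$T[free, free, drop = FALSE]
  m_free <- tryCatch(
    solve(diag(length(free)) - Tff, rep(model$lag_ns, length(free))),
    error = function(e) rep(Inf, length(free))
  )
  m <- numeric(k)
  m[free] <- m_free
  w <- model$stationary[src]
  sum(w * m[src]) / sum(w)
}

# pairwise MFPTs between a partition of the active set (original labels)
mfpt_matrix_sets <- function(model, sets) {
  n <- length(sets)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && length(sets[[i]]) > 0 && length(sets[[j]]) > 0) {
      M[i, j] <- mfpt(model, sets[[i]], sets[[j]])
    }
  }
  M
}

#' Macrostate summary table
#'
#' Per macrostate: stationary probability, member microstate count, member
#' frame count, and a representative frame — the frame nearest the center of
#' the microstate with the highest `pi * chi` inside the macrostate.
#'
#' @param macro a `macro_model`.
#' @param model the underlying `ms_model`.
#' @param micro optional `microstate_model` (enables frame counts and
#'   representatives).
#' @param proj optional `projection` (enables representative frames).
#' @return data.frame with one row per macrostate.
#' @export
macrostate_statistics <- function(macro, model, micro = NULL, proj = NULL) {
  n <- macro$n_macro
  out <- data.frame(macrostate = seq_len(n),
                    probability = macro$macro_pi,
                    n_micro = vapply(macro$macro_sets, length, integer(1)),
                    n_frames = NA_integer_,
                    representative_frame = NA_integer_)
  if (!is.null(micro)) {
    lab <- micro$labels
    for (m in seq_len(n)) {
      members <- macro$macro_sets[[m]]
      out$n_frames[m] <- sum(lab %in% members)
      if (!is.null(proj) && length(members) > 0) {
        score <- model$stationary * macro$chi[, m]
        top_local <- which.max(ifelse(macro$crisp == m, score, -Inf))
        top <- macro$active_set[top_local]
        frames <- which(lab == top)
        if (length(frames) > 0) {
          d2 <- rowSums(sweep(proj$coords[frames, , drop = FALSE], 2,
                              micro$centers[top, ])^2)
          out$representative_frame[m] <- frames[which.min(d2)]
        }
      }
    }
  }
  out
}

#' Choose a macrostate count from the implied-timescale spectrum
#'
#' Default rule: `n_macro = i + 1` for the largest i whose timescale ratio
#' `t_i / t_{i+1}` exceeds `gap` (a spectral-gap heuristic); bounded to
#' `[2, max_macro]`. The rule is a configurable convention — landscape
#' figures in this field typically report 2-5 macrostates per system.
#'
#' @param model an `ms_model`.
#' @param gap timescale ratio threshold (default 3).
#' @param max_macro upper bound (default 6).
#' @return integer macrostate count.
#' @export
choose_n_macro <- function(model, gap = 3, max_macro = 6) {
  nts <- min(max_macro, nrow(model$T) - 1)
  ts <- suppressWarnings(implied_timescales(model, nts))
  ts <- ts[is.finite(ts) & !is.na(ts)]
  if (length(ts) < 2) return(2L)
  ratios <- ts[-length(ts)] / ts[-1]
  cand <- which(ratios > gap)
  if (length(cand) == 0) return(2L)
  as.integer(min(max(cand) + 1, max_macro))
}
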