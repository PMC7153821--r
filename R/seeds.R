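# Seed selection: average-linkage clustering of a (metadynamics-diversified)
# trajectory under a distance cutoff, with medoid representatives — the stage
# that turns one long exploratory trajectory into many short-run seeds.

#' Pairwise distance matrix between trajectory frames
#'
#' @param frames a [torsion_trajectory()] (metric "dihedral") or a list of
#'   n_atoms x 3 coordinate matrices in Angstrom (metric "rmsd"; computed
#'   after optimal superposition).
#' @param metric `"dihedral"` for the North-style torsion metric or `"rmsd"`.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(frames, metric = c("dihedral", "rmsd")) {
  metric <- match.arg(metric)
  if (metric == "dihedral") {
    ang <- if (inherits(frames, "torsion_trajectory")) frames$angles else as.matrix(frames)
    n <- nrow(ang)
    if (n < 2) stop("need at least 2 frames")
    # d^2 = mean_k 2(1 - cos(a_k - b_k)); expand via sin/cos cross-products
    rad <- deg2rad(ang)
    S <- sin(rad); C <- cos(rad)
    cosdiff <- tcrossprod(C) + tcrossprod(S)       # sum_k cos(a_k - b_k)
    d2 <- 2 * (1 - cosdiff / ncol(ang))
    d2[d2 < 0] <- 0
    D <- sqrt(d2)
  } else {
    if (!is.list(frames)) stop("rmsd metric needs a list of coordinate matrices")
    n <- length(frames)
    if (n < 2) stop("need at least 2 frames")
    dims <- vapply(frames, function(x) nrow(as.matrix(x)), integer(1))
    if (length(unique(dims)) != 1) stop("rmsd requires matched atom counts")
    xyz <- do.call(rbind, lapply(frames, function(x) as.vector(t(as.matrix(x)))))
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- bio3d::rmsd(xyz[i, ], xyz[j, ], fit = TRUE)
      }
    }
  }
  diag(D) <- 0
  D
}

#' Average-linkage hierarchical clustering with a distance cutoff
#'
#' Unweighted average (UPGMA) agglomeration; merging stops when the minimum
#' average inter-cluster distance exceeds `cutoff`, so every within-cluster
#' merge happened at linkage distance <= cutoff. The analogue of clustering a
#' trajectory with an average-linkage distance-cutoff criterion to obtain
#' "a large number of clusters" of similar frames.
#'
#' @param D symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param cutoff positive distance criterion, in the units of `D`'s metric
#'   (Angstrom for rmsd, dimensionless for the dihedral metric).
#' @return a `cluster_result`: `labels` (1-based, in order of first
#'   appearance), `n_clusters`, `sizes`, `cutoff`, and `representatives`
#'   (filled by [pick_representatives()], NULL here).
#' @export
average_linkage_cluster <- function(D, cutoff) {
  D <- as.matrix(D)
  if (anyNA(D)) stop("distance matrix contains NA")
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- nrow(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, h = cutoff)
  # relabel in order of first appearance for determinism
  labels <- match(raw, unique(raw))
  structure(list(labels = labels, n_clusters = max(labels),
                 sizes = tabulate(labels), cutoff = cutoff,
                 representatives = NULL),
            class = "cluster_result")
}

#' Medoid representative of each cluster
#'
#' The representative of a cluster is the frame minimizing the sum of
#' distances to all members of its cluster; ties break to the lowest frame
#' index.
#'
#' @param result a `cluster_result`.
#' @param D the distance matrix the clustering was computed from.
#' @return the `cluster_result` with `representatives`: one frame index per
#'   cluster, ordered by cluster label.
#' @export
pick_representatives <- function(result, D) {
  D <- as.matrix(D)
  if (length(result$labels) != nrow(D)) stop("clustering inconsistent with D")
  reps <- vapply(seq_len(result$n_clusters), function(cl) {
    members <- which(result$labels == cl)
    sums <- rowSums(D[members, members, drop = FALSE])
    members[which.min(sums)]
  }, integer(1))
  result$representatives <- reps
  result
}
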