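# Free-energy surfaces in tIC space, projection of reference (canonical
# median) conformations, their assignment to kinetic minima, and the
# nearest-neighbor distance report.

#' Free-energy surface on a 2-D tIC grid
#'
#' Histograms the projected frames on a `bins x bins` grid spanning the data
#' range padded by `pad` on each side, and converts occupancy to free energy
#' `F = -ln(p / p_max)` in kT (so the global minimum is exactly 0). With
#' `weights`, the histogram uses per-frame stationary reweighting — seeded
#' short trajectories are not an equilibrium sample, so the default pipeline
#' passes MSM-derived weights (see [stationary_frame_weights()]). Unoccupied
#' bins are flagged, never extrapolated.
#'
#' @param proj a `projection` or frames x 2 coordinate matrix.
#' @param weights optional per-frame weights (any positive scale).
#' @param bins bins per axis (default 100).
#' @param temperature Kelvin, for the kcal/mol conversion (default 300).
#' @param pad fractional range padding per side (default 0.05).
#' @return a `free_energy_surface`: `xedges`, `yedges`, `prob` (normalized
#'   over occupied bins), `F_kT`, `F_kcal`, `occupied`, `temperature`.
#' @export
free_energy_surface <- function(proj, weights = NULL, bins = 100,
                                temperature = 300, pad = 0.05) {
  X <- if (inherits(proj, "projection")) proj$coords else as.matrix(proj)
  if (nrow(X) == 0) stop("empty projection")
  if (ncol(X) < 2) stop("need at least two tIC coordinates for a surface")
  X <- X[, 1:2, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (length(weights) != nrow(X)) stop("weights length must match frame count")
  bins <- rep(bins, length.out = 2)
  edges <- lapply(1:2, function(j) {
    r <- range(X[, j])
    span <- diff(r)
    if (span == 0) span <- 1
    seq(r[1] - pad * span, r[2] + pad * span, length.out = bins[j] + 1)
  })
  ix <- findInterval(X[, 1], edges[[1]], rightmost.closed = TRUE)
  iy <- findInterval(X[, 2], edges[[2]], rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1), bins[1]); iy <- pmin(pmax(iy, 1), bins[2])
  P <- matrix(0, bins[1], bins[2])
  for (b in seq_len(nrow(X))) P[ix[b], iy[b]] <- P[ix[b], iy[b]] + weights[b]
  P <- P / sum(P)
  occ <- P > 0
  if (sum(occ) < 2) stop("fewer than 2 occupied bins; surface is degenerate")
  F_kT <- matrix(NA_real_, bins[1], bins[2])
  F_kT[occ] <- -log(P[occ] / max(P))
  kB_kcal <- 0.0019872041  # kcal/(mol K)
  structure(list(xedges = edges[[1]], yedges = edges[[2]], prob = P,
                 F_kT = F_kT, F_kcal = F_kT * kB_kcal * temperature,
                 occupied = occ, temperature = temperature),
            class = "free_energy_surface")
}

#' Stationary reweighting of frames via an MSM
#'
#' Frame weight proportional to pi of the frame's microstate divided by the
#' number of frames in that microstate, so every microstate contributes its
#' equilibrium probability. Frames of microstates trimmed off the active set
#' are reassigned, for weighting and coloring only, to the nearest active
#' center.
#'
#' @param model an `ms_model`.
#' @param micro the `microstate_model` it was built from.
#' @param proj the `projection` (needed to reassign trimmed frames).
#' @return normalized per-frame weight vector.
#' @export
stationary_frame_weights <- function(model, micro, proj = NULL) {
  lab <- micro$labels
  act <- model$active_set
  if (!all(lab %in% act)) {
    if (is.null(proj)) stop("projection required to reassign trimmed frames")
    bad <- which(!lab %in% act)
    d2 <- assign_d2(proj$coords[bad, , drop = FALSE],
                    micro$centers[act, , drop = FALSE])
    lab[bad] <- act[max.col(-d2, ties.method = "first")]
  }
  pi_of <- stats::setNames(model$stationary, act)
  counts <- table(factor(lab, levels = act))
  w <- pi_of[as.character(lab)] / as.numeric(counts[as.character(lab)])
  unname(w / sum(w))
}

#' Project reference conformations into tIC space
#'
#' Featurizes each reference torsion vector (sin/cos) and applies the tICA
#' projection — the same map used for trajectory frames, so references are
#' directly comparable to the landscape.
#'
#' @param refs list of [reference_conformation()] objects.
#' @param tica_model the fitted `tica_model`.
#' @return data.frame: name plus one column per tIC (tic1, tic2, ...).
#' @export
project_references <- function(refs, tica_model) {
  coords <- t(vapply(refs, function(r) {
    f <- featurize(matrix(r$torsions, nrow = 1))$features
    if (ncol(f) != length(tica_model$mean)) {
      stop(sprintf("reference '%s': torsion count does not match the featurization", r$name))
    }
    drop(tica_project(tica_model, f))
  }, numeric(tica_model$n_components)))
  out <- data.frame(name = vapply(refs, function(r) r$name, character(1)),
                    coords)
  names(out)[-1] <- paste0("tic", seq_len(ncol(coords)))
  rownames(out) <- NULL
  out
}

#' Assign references to kinetic minima (macrostates)
#'
#' Each reference maps to its nearest microstate center (Euclidean in tIC
#' space) and thence to that microstate's crisp macrostate. References whose
#' distance to the nearest occupied free-energy bin center exceeds
#' `outlier_cutoff` are reported as not sampled. The headline output is the
#' grouping: references sharing a macrostate share a kinetic minimum.
#'
#' @param ref_coords data.frame from [project_references()] (uses the first
#'   two tIC columns for the outlier test, all for microstate matching).
#' @param micro a `microstate_model`.
#' @param macro a `macro_model`.
#' @param fes optional `free_energy_surface` for the outlier test.
#' @param outlier_cutoff tIC-space distance beyond which a reference counts
#'   as unsampled; default 3x the median nearest-neighbor spacing of occupied
#'   bin centers.
#' @return a `kinetic_grouping`: `assignment` (data.frame: name, microstate,
#'   macrostate, dist_to_data, sampled), `groups` (list of reference-name
#'   vectors per macrostate with members), `outliers` (names).
#' @export
assign_references_to_kinetics <- function(ref_coords, micro, macro, fes = NULL,
                                          outlier_cutoff = NULL) {
  cc <- as.matrix(ref_coords[, grep("^tic", names(ref_coords)), drop = FALSE])
  d2 <- assign_d2(cc[, seq_len(ncol(micro$centers)), drop = FALSE], micro$centers)
  nearest_micro <- max.col(-d2, ties.method = "first")
  act_pos <- match(nearest_micro, macro$active_set)
  macrostate <- ifelse(is.na(act_pos), NA_integer_, macro$crisp[act_pos])
  sampled <- rep(TRUE, nrow(cc))
  dist_to_data <- rep(NA_real_, nrow(cc))
  if (!is.null(fes)) {
    xc <- (fes$xedges[-1] + fes$xedges[-length(fes$xedges)]) / 2
    yc <- (fes$yedges[-1] + fes$yedges[-length(fes$yedges)]) / 2
    occ <- which(fes$occupied, arr.ind = TRUE)
    centers <- cbind(xc[occ[, 1]], yc[occ[, 2]])
    if (is.null(outlier_cutoff)) {
      nn <- nn_spacing(centers)
      outlier_cutoff <- 3 * nn
    }
    dd <- assign_d2(cc[, 1:2, drop = FALSE], centers)
    dist_to_data <- sqrt(apply(dd, 1, min))
    sampled <- dist_to_data <= outlier_cutoff
  }
  assignment <- data.frame(name = ref_coords$name, microstate = nearest_micro,
                           macrostate = macrostate,
                           dist_to_data = dist_to_data, sampled = sampled)
  groups <- split(assignment$name[sampled], assignment$macrostate[sampled])
  structure(list(assignment = assignment, groups = groups,
                 outliers = assignment$name[!sampled],
                 outlier_cutoff = outlier_cutoff),
            class = "kinetic_grouping")
}

# median nearest-neighbor distance among points (rows)
nn_spacing <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(Inf)
  if (n > 4000) pts <- pts[seq(1, n, length.out = 4000), , drop = FALSE]
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  stats::median(apply(D, 1, min))
}

#' @export
print.kinetic_grouping <- function(x, ...) {
  cat(sprintf("<kinetic_grouping: %d references in %d kinetic groups, %d unsampled>\n",
              nrow(x$assignment), length(x$groups), length(x$outliers)))
  for (g in seq_along(x$groups)) {
    cat(sprintf("  minimum %s: %s\n", names(x$groups)[g],
                paste(x$groups[[g]], collapse = ", ")))
  }
  if (length(x$outliers) > 0) {
    cat("  not sampled:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nearest-neighbor report for reference conformations
#'
#' For each reference, the minimum North-style dihedral distance over all
#' trajectory frames, with the frame attaining it (earliest frame on ties) —
#' how close the simulated ensemble approaches each canonical median.
#'
#' @param refs list of [reference_conformation()] objects.
#' @param trajs list of [torsion_trajectory()] objects.
#' @return data.frame: reference, min_distance, trajectory, frame.
#' @export
nearest_neighbor_report <- function(refs, trajs) {
  if (inherits(trajs, "torsion_trajectory")) trajs <- list(trajs)
  rows <- lapply(refs, function(r) {
    best <- c(dist = Inf, traj = NA_integer_, frame = NA_integer_)
    for (ti in seq_along(trajs)) {
      ang <- trajs[[ti]]$angles
      if (ncol(ang) != length(r$torsions)) {
        stop(sprintf("reference '%s': torsion length %d does not match trajectory (%d angles)",
                     r$name, length(r$torsions), ncol(ang)))
      }
      d <- deg2rad(sweep(ang, 2, r$torsions))
      dist <- sqrt(rowMeans(2 * (1 - cos(d))))
      i <- which.min(dist)
      if (dist[i] < best["dist"]) {
        best <- c(dist = dist[i], traj = ti, frame = i)
      }
    }
    data.frame(reference = r$name, min_distance = best[["dist"]],
               trajectory = as.integer(best[["traj"]]),
               frame = as.integer(best[["frame"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
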