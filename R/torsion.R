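# Torsion-angle containers, dihedral geometry, periodic featurization, the
# metadynamics collective variable, and the North-style dihedral metric.

#' Construct a torsion trajectory
#'
#' Per-frame backbone phi/psi angles for one CDR loop. Angles are stored in
#' degrees, wrapped to (-180, 180], with columns ordered phi_1, psi_1, ...,
#' phi_L, psi_L for a loop of L residues.
#'
#' @param angles frames x 2L numeric matrix of angles in degrees.
#' @param angle_names optional column labels; defaults to phi_i/psi_i pairs.
#' @param frame_dt nominal time per frame in nanoseconds.
#' @param loop_id free-text label for the loop.
#' @return an object of class `torsion_trajectory`.
#' @export
torsion_trajectory <- function(angles, angle_names = NULL, frame_dt = 1,
                               loop_id = "loop") {
  angles <- as.matrix(angles)
  if (nrow(angles) < 1) stop("a torsion trajectory needs at least one frame")
  if (anyNA(angles)) stop("torsion trajectory contains missing values")
  if (ncol(angles) %% 2 != 0) stop("angle count must be 2L (phi/psi per residue)")
  angles <- wrap_angle(angles)
  if (is.null(angle_names)) angle_names <- phi_psi_names(ncol(angles) / 2)
  if (length(angle_names) != ncol(angles)) stop("angle_names length mismatch")
  colnames(angles) <- angle_names
  structure(
    list(angles = angles, angle_names = angle_names,
         frame_dt = frame_dt, loop_id = loop_id),
    class = "torsion_trajectory"
  )
}

#' @export
print.torsion_trajectory <- function(x, ...) {
  cat(sprintf("<torsion_trajectory '%s': %d frames x %d angles (L = %d), %.3g ns/frame>\n",
              x$loop_id, nrow(x$angles), ncol(x$angles), ncol(x$angles) / 2, x$frame_dt))
  invisible(x)
}

#' Standard phi/psi column names for a loop of length L
#' @param L residue count.
#' @return character vector "phi_1","psi_1",...,"phi_L","psi_L".
#' @export
phi_psi_names <- function(L) {
  as.vector(rbind(paste0("phi_", seq_len(L)), paste0("psi_", seq_len(L))))
}

#' Loop definition
#'
#' Which residues of a chain constitute the CDR loop under analysis.
#'
#' @param chain_id one-letter chain identifier.
#' @param first,last inclusive author residue numbers of the loop.
#' @return a `loop_definition` object with derived length.
#' @export
loop_definition <- function(chain_id, first, last) {
  if (last < first) stop("last residue must be >= first")
  structure(list(chain_id = chain_id, first = first, last = last,
                 length = last - first + 1L),
            class = "loop_definition")
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: 0 for cis (eclipsed), 180 for trans. Computed with
#' the projection formula `atan2(|b2| b1 . (b2 x b3), (b1 x b2) . (b2 x b3))`,
#' numerically stable away from degenerate geometry.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return the torsion angle in degrees, in (-180, 180].
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  lens <- c(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))
  if (any(lens < 1e-8)) stop("degenerate geometry: zero-length bond vector")
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 * lens[1] * lens[2] ||
      sqrt(sum(n2^2)) < 1e-8 * lens[2] * lens[3]) {
    stop("degenerate geometry: collinear bond vectors")
  }
  y <- lens[2] * sum(b1 * n2)
  x <- sum(n1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Extract loop phi/psi torsions from a PDB structure
#'
#' phi of residue i uses C(i-1), N(i), CA(i), C(i); psi uses N(i), CA(i),
#' C(i), N(i+1). The residues flanking the loop supply the terminal
#' dependencies, so the structure must contain `first - 1` and `last + 1`.
#' Multi-model files yield one frame per model.
#'
#' @param structure a `bio3d` pdb object or a path to a PDB file.
#' @param loop a [loop_definition()].
#' @return a [torsion_trajectory()] with one frame per model.
#' @export
extract_loop_torsions <- function(structure, loop) {
  if (is.character(structure)) {
    structure <- bio3d::read.pdb(structure, multi = TRUE, verbose = FALSE)
  }
  atoms <- structure$atom
  xyz <- structure$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atom_row <- function(resno, elety) {
    i <- which(atoms$chain == loop$chain_id & atoms$resno == resno &
                 atoms$elety == elety)
    if (length(i) == 0) {
      stop(sprintf("missing backbone atom %s of residue %d (chain %s)",
                   elety, resno, loop$chain_id))
    }
    i[1]
  }
  res <- seq(loop$first, loop$last)
  need <- rbind(
    data.frame(resno = loop$first - 1L, elety = "C"),
    expand.grid(elety = c("N", "CA", "C"), resno = res,
                stringsAsFactors = FALSE)[, c("resno", "elety")],
    data.frame(resno = loop$last + 1L, elety = "N")
  )
  idx <- mapply(atom_row, need$resno, need$elety)
  n_models <- nrow(xyz)
  L <- loop$length
  out <- matrix(NA_real_, n_models, 2L * L)
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    p <- coords[idx, , drop = FALSE]
    # p rows: C(first-1), then N,CA,C per loop residue, then N(last+1);
    # for residue i: C(i-1) = row 3i-2, N(i) = 3i-1, CA(i) = 3i, C(i) = 3i+1
    for (i in seq_len(L)) {
      o <- 3L * i - 2L
      out[m, 2L * i - 1L] <- compute_dihedral(p[o, ], p[o + 1L, ], p[o + 2L, ], p[o + 3L, ])
      out[m, 2L * i] <- compute_dihedral(p[o + 1L, ], p[o + 2L, ], p[o + 3L, ], p[o + 4L, ])
    }
  }
  torsion_trajectory(out, phi_psi_names(L), frame_dt = 1,
                     loop_id = sprintf("%s:%d-%d", loop$chain_id, loop$first, loop$last))
}

#' Periodic sin/cos featurization of torsion angles
#'
#' Maps each angle theta to the pair (sin theta, cos theta), removing the
#' artificial discontinuity at +/-180 degrees. Column order is
#' (sin t1, cos t1, sin t2, cos t2, ...). The map is invertible via
#' [defeaturize()].
#'
#' @param traj a [torsion_trajectory()] or a frames x 2L angle matrix (degrees).
#' @return a `feature_trajectory`: frames x 4L matrix plus provenance.
#' @export
featurize <- function(traj) {
  ang <- if (inherits(traj, "torsion_trajectory")) traj$angles else as.matrix(traj)
  rad <- deg2rad(ang)
  n <- ncol(ang)
  feats <- matrix(NA_real_, nrow(ang), 2L * n)
  feats[, 2L * seq_len(n) - 1L] <- sin(rad)
  feats[, 2L * seq_len(n)] <- cos(rad)
  nm <- colnames(ang)
  if (is.null(nm)) nm <- paste0("theta_", seq_len(n))
  colnames(feats) <- as.vector(rbind(paste0("sin_", nm), paste0("cos_", nm)))
  structure(list(features = feats,
                 frame_dt = if (inherits(traj, "torsion_trajectory")) traj$frame_dt else 1,
                 source = if (inherits(traj, "torsion_trajectory")) traj$loop_id else NA_character_),
            class = "feature_trajectory")
}

#' Invert sin/cos featurization back to angles
#'
#' @param features a `feature_trajectory` or frames x 4L sin/cos matrix.
#' @return frames x 2L matrix of angles in degrees, (-180, 180].
#' @export
defeaturize <- function(features) {
  f <- if (inherits(features, "feature_trajectory")) features$features else as.matrix(features)
  n <- ncol(f) / 2L
  s <- f[, 2L * seq_len(n) - 1L, drop = FALSE]
  cc <- f[, 2L * seq_len(n), drop = FALSE]
  wrap_angle(rad2deg(atan2(s, cc)))
}

#' Metadynamics collective variable: weighted sums of sin and cos of psi
#'
#' The biased-sampling collective variable used to diversify loop seeds: a
#' linear combination of the sines and cosines of the psi torsions of the
#' primary loop (optionally extended with a neighboring loop's psi angles).
#'
#' @param psi vector of psi angles in degrees.
#' @param weights per-term coefficients; default all 1.
#' @return named numeric vector c(cv_sin, cv_cos) with
#'   cv_sin = sum w_i sin psi_i and cv_cos = sum w_i cos psi_i.
#' @export
metadynamics_cv <- function(psi, weights = rep(1, length(psi))) {
  if (length(weights) != length(psi)) {
    stop("weights length must equal the number of psi angles")
  }
  rad <- deg2rad(psi)
  c(cv_sin = sum(weights * sin(rad)), cv_cos = sum(weights * cos(rad)))
}

#' North-style dihedral distance between two torsion vectors
#'
#' `d(a, b) = sqrt( (1/n) * sum_k 2 (1 - cos(a_k - b_k)) )` over the n = 2L
#' backbone angles. The per-angle average makes distances comparable across
#' loop lengths; the maximum (all angles flipped by 180 degrees) is 2, and a
#' single 180-degree flip in an L-residue loop gives sqrt(4 / (2L)).
#'
#' @param a,b torsion vectors in degrees, equal length.
#' @return non-negative scalar distance (dimensionless).
#' @export
dihedral_distance <- function(a, b) {
  if (length(a) != length(b)) stop("torsion vectors must have equal length")
  d <- deg2rad(a - b)
  sqrt(mean(2 * (1 - cos(d))))
}

#' Reference conformation (canonical cluster median stand-in)
#'
#' @param name identifier, e.g. a canonical cluster label plus PDB code.
#' @param torsions vector of 2L backbone angles in degrees.
#' @param source free-text provenance.
#' @return a `reference_conformation` object.
#' @export
reference_conformation <- function(name, torsions, source = "") {
  structure(list(name = name, torsions = wrap_angle(as.numeric(torsions)),
                 source = source),
            class = "reference_conformation")
}

#' @export
print.reference_conformation <- function(x, ...) {
  cat(sprintf("<reference_conformation '%s': %d angles>\n", x$name, length(x$torsions)))
  invisible(x)
}
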