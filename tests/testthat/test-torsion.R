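# Dihedral geometry, periodic featurization, the metadynamics collective
# variable, and the North-style dihedral metric.

test_that("planar quadruples give the cis/trans limits", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(abs(compute_dihedral(p1, p2, p3, c(-1, 0, 0))), 180, tolerance = 1e-12)
})

test_that("dihedral matches an independent implementation on random quadruples", {
  set.seed(42)
  for (i in 1:20) {
    q <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    mine <- compute_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4)
    expect_equal(wrap_angle(mine - ref), 0, tolerance = 1e-9)
  }
})

test_that("degenerate geometry is rejected", {
  p <- c(0, 0, 0)
  expect_error(compute_dihedral(p, p, c(1, 0, 0), c(2, 0, 0)), "zero-length")
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("ideal helix coordinates round-trip through PDB extraction", {
  tab <- build_backbone(9, phi = -57, psi = -47)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(tab, path)
  traj <- extract_loop_torsions(path, loop_definition("A", 3, 7))
  expect_equal(nrow(traj$angles), 1)
  expect_equal(ncol(traj$angles), 10)
  expect_lt(max(abs(traj$angles[1, seq(1, 10, 2)] - (-57))), 0.5)
  expect_lt(max(abs(traj$angles[1, seq(2, 10, 2)] - (-47))), 0.5)
})

test_that("multi-model PDBs give one identical frame per model", {
  tab <- build_backbone(7, phi = -75, psi = 145)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(tab, path, n_models = 3)
  traj <- extract_loop_torsions(path, loop_definition("A", 2, 6))
  expect_equal(nrow(traj$angles), 3)
  expect_equal(traj$angles[1, ], traj$angles[2, ])
  expect_equal(traj$angles[1, ], traj$angles[3, ])
})

test_that("a loop lacking its flanking residue errors by name", {
  tab <- build_backbone(6, phi = -57, psi = -47)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(tab, path)
  expect_error(extract_loop_torsions(path, loop_definition("A", 1, 4)),
               "residue 0")
  expect_error(extract_loop_torsions(path, loop_definition("B", 2, 4)),
               "chain B")
})

test_that("featurization hits the cardinal points and inverts exactly", {
  f <- featurize(matrix(c(0, 180, 90), nrow = 1))$features
  expect_equal(unname(f), matrix(c(0, 1, 0, -1, 1, 0), nrow = 1),
               tolerance = 1e-12)
  set.seed(7)
  ang <- matrix(stats::runif(1000, -179.999, 180), ncol = 4)
  back <- defeaturize(featurize(ang))
  expect_lt(max(abs(wrap_angle(back - ang))), 1e-9)
})

test_that("sin^2 + cos^2 stays 1 and wrapping changes nothing", {
  set.seed(1)
  ang <- matrix(stats::runif(200, -180, 180), ncol = 2)
  f <- featurize(ang)$features
  s2 <- f[, c(1, 3)]^2 + f[, c(2, 4)]^2
  expect_lt(max(abs(s2 - 1)), 1e-12)
  f2 <- featurize(ang + 360)$features
  expect_lt(max(abs(f - f2)), 1e-9)
  expect_lt(abs(dihedral_distance(ang[1, ], ang[2, ]) -
                dihedral_distance(ang[1, ] + 360, ang[2, ])), 1e-9)
})

test_that("collective variable sums match a term-by-term oracle", {
  expect_equal(metadynamics_cv(rep(0, 5)), c(cv_sin = 0, cv_cos = 5))
  expect_equal(metadynamics_cv(c(90, -90)), c(cv_sin = 0, cv_cos = 0),
               tolerance = 1e-12)
  set.seed(9)
  psi <- stats::runif(11, -180, 180)
  w <- stats::rnorm(11)
  oracle <- c(0, 0)
  for (i in 1:11) {
    oracle <- oracle + w[i] * c(sin(psi[i] * pi / 180), cos(psi[i] * pi / 180))
  }
  expect_equal(unname(metadynamics_cv(psi, w)), oracle, tolerance = 1e-12)
  expect_error(metadynamics_cv(psi, w[1:3]), "length")
})

test_that("dihedral distance closed forms and metric properties hold", {
  a <- stats::runif(26, -180, 180)
  expect_equal(dihedral_distance(a, a), 0)
  b <- a; b[4] <- wrap_angle(b[4] + 180)
  expect_equal(dihedral_distance(a, b), sqrt(4 / 26), tolerance = 1e-12)
  expect_equal(dihedral_distance(a, wrap_angle(a + 180)), 2, tolerance = 1e-12)
  expect_error(dihedral_distance(a, a[1:10]), "equal length")
  set.seed(12)
  for (i in 1:100) {
    x <- stats::runif(8, -180, 180); y <- stats::runif(8, -180, 180)
    z <- stats::runif(8, -180, 180)
    expect_equal(dihedral_distance(x, y), dihedral_distance(y, x))
    expect_lte(dihedral_distance(x, z),
               dihedral_distance(x, y) + dihedral_distance(y, z) + 1e-12)
    expect_equal(dihedral_distance(x, y), naive_dihedral_distance(x, y),
                 tolerance = 1e-12)
  }
})
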