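# Free-energy surfaces, reference projection, kinetic grouping, and the
# nearest-neighbor distance report.

test_that("uniform occupancy gives a flat zero surface", {
  g <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
  fes <- free_energy_surface(as.matrix(g), bins = 10, pad = 0.05)
  expect_lt(max(fes$F_kT[fes$occupied]), 1e-12)
})

test_that("two-bin occupancy reproduces the closed-form free energy gap", {
  X <- cbind(c(rep(0, 8), rep(10, 2)), c(rep(0, 8), rep(10, 2)))
  fes <- free_energy_surface(X, bins = 2, temperature = 300, pad = 0)
  F_occ <- sort(fes$F_kT[fes$occupied])
  expect_equal(F_occ[1], 0)
  expect_equal(F_occ[2], log(4), tolerance = 1e-12)
  Fk <- sort(fes$F_kcal[fes$occupied])
  expect_equal(Fk[2], log(4) * 0.0019872041 * 300, tolerance = 1e-6)
})

test_that("exp(-F) renormalized over occupied bins recovers the histogram", {
  set.seed(9)
  X <- matrix(stats::rnorm(2000), ncol = 2)
  fes <- free_energy_surface(X, bins = 20)
  p <- exp(-fes$F_kT[fes$occupied])
  p <- p / sum(p)
  expect_lt(max(abs(p - fes$prob[fes$occupied] / sum(fes$prob[fes$occupied]))), 1e-12)
})

test_that("planted 80/20 weights give a basin gap near ln 4", {
  Ttrue <- matrix(c(0.99, 0.01, 0.04, 0.96), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(Ttrue), c(0.8, 0.2))
  means <- default_loop_states(2, 6)
  spec <- synthetic_spec(2, means, 32, Ttrue, 100, 600, seed = 17,
                         start_mode = "stationary")
  sim <- generate_torsion_ensemble(spec)
  feats <- lapply(sim$trajectories, featurize)
  tica <- estimate_tica(feats, lag = 5, n_components = 2)
  proj <- tica_project(tica, feats)
  micro <- kmeans_discretize(proj, 30, seed = 42)
  m <- estimate_reversible_T(count_transitions(micro$dtrajs, 5, n_states = 30))
  w <- stationary_frame_weights(m, micro, proj)
  # total reweighted mass per hidden basin
  hid <- unlist(sim$ground_truth$state_labels)
  mass <- c(sum(w[hid == 1]), sum(w[hid == 2]))
  dF <- -log(mass[2] / mass[1])
  expect_lt(abs(dF - log(4)), 0.1)
})

test_that("reference projection is deterministic and lands inside the cloud", {
  spec <- synthetic_spec(1, default_loop_states(1, 5), 32, matrix(1),
                         10, 300, seed = 23)
  sim <- generate_torsion_ensemble(spec)
  feats <- lapply(sim$trajectories, featurize)
  tica <- estimate_tica(feats, lag = 2, n_components = 2)
  proj <- tica_project(tica, feats)
  refs <- plant_reference_conformations(spec, list(mean_ref = 1, dup = 1))
  rc <- project_references(refs, tica)
  expect_equal(rc[1, -1], rc[2, -1], ignore_attr = TRUE)
  # the basin-center conformation projects well inside the (unit-variance)
  # single-state cloud, within one projected standard deviation of its center
  y <- as.numeric(rc[1, -1])
  center <- colMeans(proj$coords)
  expect_lt(max(abs(y - center)), 1)
  expect_true(all(y > apply(proj$coords, 2, min) &
                  y < apply(proj$coords, 2, max)))
  bad <- list(reference_conformation("short", c(0, 0)))
  expect_error(project_references(bad, tica), "short")
})

test_that("kinetic grouping co-groups same-state references and flags outliers", {
  spec <- small_spec(seed = 37, n_traj = 50, traj_len = 300)
  sim <- generate_torsion_ensemble(spec)
  refs <- plant_reference_conformations(
    spec, list(r1 = 1, r2 = 1, r3 = 2, r4 = 3, r5 = 4))
  feats <- lapply(sim$trajectories, featurize)
  tica <- estimate_tica(feats, lag = 5, n_components = 3)
  proj <- tica_project(tica, feats)
  micro <- kmeans_discretize(proj, 60, seed = 42)
  m <- estimate_reversible_T(count_transitions(micro$dtrajs, 5, n_states = 60))
  mac <- pcca_plus(m, 4)
  fes <- free_energy_surface(proj, stationary_frame_weights(m, micro, proj))
  rc <- project_references(refs, tica)
  grp <- assign_references_to_kinetics(rc, micro, mac, fes)
  a <- grp$assignment
  expect_equal(a$macrostate[a$name == "r1"], a$macrostate[a$name == "r2"])
  macs <- a$macrostate[match(c("r1", "r3", "r4", "r5"), a$name)]
  expect_equal(length(unique(macs)), 4)
  expect_equal(length(grp$groups), 4)
  expect_equal(length(grp$outliers), 0)
  # a far-away reference is reported as not sampled
  far <- rc[1, ]
  far$name <- "far"
  far[, -1] <- far[, -1] + 10 * diff(range(proj$coords[, 1]))
  grp2 <- assign_references_to_kinetics(rbind(rc, far), micro, mac, fes)
  expect_true("far" %in% grp2$outliers)
})

test_that("nearest-neighbor report matches brute force and finds exact frames", {
  spec <- small_spec(seed = 43, n_traj = 3, traj_len = 40)
  sim <- generate_torsion_ensemble(spec)
  trajs <- sim$trajectories
  target <- trajs[[2]]$angles[17, ]
  refs <- c(plant_reference_conformations(spec, list(s1 = 1, s2 = 2)),
            list(exact = reference_conformation("exact", target)))
  rep_tab <- nearest_neighbor_report(refs, trajs)
  expect_equal(rep_tab$min_distance[rep_tab$reference == "exact"], 0, tolerance = 1e-12)
  expect_equal(rep_tab$trajectory[rep_tab$reference == "exact"], 2L)
  expect_equal(rep_tab$frame[rep_tab$reference == "exact"], 17L)
  for (r in seq_along(refs)) {
    best <- Inf
    for (tr in trajs) for (f in seq_len(nrow(tr$angles))) {
      best <- min(best, naive_dihedral_distance(refs[[r]]$torsions, tr$angles[f, ]))
    }
    expect_equal(rep_tab$min_distance[r], best, tolerance = 1e-12)
  }
  short <- list(reference_conformation("bad", c(1, 2)))
  expect_error(nearest_neighbor_report(short, trajs), "bad")
})
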