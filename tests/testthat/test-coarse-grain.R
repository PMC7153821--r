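# PCCA+ coarse-graining, macrostate statistics, mean first passage times.

make_model <- function(T, lag_ns = 10) {
  structure(list(T = T, stationary = stationary_distribution(T),
                 lag = as.integer(lag_ns), lag_ns = lag_ns, frame_dt = 1,
                 active_set = seq_len(nrow(T)), fraction_retained = 1,
                 counts = T * 1000),
            class = "ms_model")
}

test_that("PCCA+ recovers the blocks of a nearly block-diagonal chain", {
  eps <- 1e-3
  T <- rbind(c(0.70 - eps, 0.30, eps, 0),
             c(0.30, 0.70 - eps, 0, eps),
             c(eps, 0, 0.60 - eps, 0.40),
             c(0, eps, 0.40, 0.60 - eps))
  m <- make_model(T)
  mac <- pcca_plus(m, 2)
  expect_true(same_partition(mac$crisp, c(1, 1, 2, 2)))
  expect_lt(max(abs(rowSums(mac$chi) - 1)), 1e-8)
  expect_true(all(mac$chi >= 0))
  expect_equal(sum(mac$macro_pi), 1, tolerance = 1e-10)
  # memberships of block members are nearly crisp
  expect_gt(min(apply(mac$chi, 1, max)), 0.95)
})

test_that("n_macro equal to the state count gives an identity-like membership", {
  set.seed(61)
  C <- matrix(stats::rpois(25, 15) + 1, 5, 5) + diag(400, 5)  # metastable: positive spectrum
  m <- estimate_reversible_T(C)
  mac <- pcca_plus(m, 5)
  expect_true(all(sort(mac$crisp) == 1:5))
  expect_lt(max(abs(mac$chi[cbind(seq_len(5), mac$crisp)] - 1)), 1e-6)
})

test_that("coarse-grained probabilities of a block-metastable chain match the blocks", {
  eps <- 5e-4
  T <- rbind(c(0.9 - eps, 0.1, eps, 0),
             c(0.05, 0.95 - eps, 0, eps),
             c(eps, 0, 0.8 - eps, 0.2),
             c(0, eps, 0.2, 0.8 - eps))
  m <- make_model(T)
  mac <- pcca_plus(m, 2)
  pi_ <- m$stationary
  block_pi <- c(sum(pi_[1:2]), sum(pi_[3:4]))
  expect_equal(sort(mac$macro_pi), sort(block_pi), tolerance = 1e-3)
})

test_that("MFPT matches the 2-state closed form and symmetry", {
  T <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  m <- make_model(T, lag_ns = 10)
  expect_equal(mfpt(m, 1, 2), 10 / 0.2, tolerance = 1e-10)
  expect_equal(mfpt(m, 1, 2), mfpt(m, 2, 1))
  expect_error(mfpt(m, 1, 1), "disjoint")
})

test_that("MFPT matches a Monte-Carlo first-passage oracle on a 6-state chain", {
  set.seed(71)
  C <- matrix(stats::rpois(36, 8) + 1, 6, 6)
  m <- make_model(estimate_reversible_T(C)$T, lag_ns = 1)
  val <- mfpt(m, 1, 4)
  steps <- mc_mfpt_steps(m$T, 1, 4, 1e5)
  se <- stats::sd(steps) / sqrt(length(steps))
  expect_lt(abs(val - mean(steps)), 3 * se + 1e-9)
})

test_that("unreachable targets give infinite MFPT", {
  T <- diag(2)
  m <- structure(list(T = T, stationary = c(0.5, 0.5), lag = 1L, lag_ns = 1,
                      frame_dt = 1, active_set = 1:2, fraction_retained = 1),
                 class = "ms_model")
  expect_equal(mfpt(m, 1, 2), Inf)
})

test_that("stationary flux balance holds between two macrostates", {
  spec <- small_spec(seed = 47, n_traj = 60, traj_len = 400)
  sim <- generate_torsion_ensemble(spec)
  feats <- lapply(sim$trajectories, featurize)
  tica <- estimate_tica(feats, lag = 5, n_components = 3)
  proj <- tica_project(tica, feats)
  micro <- kmeans_discretize(proj, 40, seed = 42)
  m <- estimate_reversible_T(count_transitions(micro$dtrajs, 5, n_states = 40))
  mac <- pcca_plus(m, 2)
  fluxAB <- mac$macro_pi[1] / mac$mfpt_matrix[1, 2]
  fluxBA <- mac$macro_pi[2] / mac$mfpt_matrix[2, 1]
  expect_lt(abs(fluxAB - fluxBA) / fluxBA, 0.20)
})

test_that("macrostate statistics tabulate probabilities and representatives", {
  spec <- small_spec(seed = 53, n_traj = 30, traj_len = 300)
  sim <- generate_torsion_ensemble(spec)
  feats <- lapply(sim$trajectories, featurize)
  tica <- estimate_tica(feats, lag = 5, n_components = 3)
  proj <- tica_project(tica, feats)
  micro <- kmeans_discretize(proj, 50, seed = 42)
  m <- estimate_reversible_T(count_transitions(micro$dtrajs, 5, n_states = 50))
  mac <- pcca_plus(m, 4)
  tab <- macrostate_statistics(mac, m, micro, proj)
  expect_equal(sum(tab$probability), 1, tolerance = 1e-10)
  expect_equal(sum(tab$n_micro), length(m$active_set))
  expect_true(all(!is.na(tab$representative_frame)))
  # representative frames carry the macrostate they represent
  for (r in seq_len(nrow(tab))) {
    micro_of_rep <- micro$labels[tab$representative_frame[r]]
    expect_equal(mac$crisp[match(micro_of_rep, m$active_set)], tab$macrostate[r])
  }
  # planted 4-state system: hidden-state probabilities ~ uniform are recovered
  hid <- unlist(sim$ground_truth$state_labels)
  expect_lt(max(abs(sort(tab$probability) -
                    sort(sim$ground_truth$true_stationary))), 0.05)
})
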