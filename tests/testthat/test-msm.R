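# MSM core: k-means discretization, transition counting, connectivity,
# reversible estimation, implied timescales, Chapman-Kolmogorov.

test_that("k-means degenerate settings behave exactly", {
  set.seed(14)
  X <- matrix(stats::runif(20), ncol = 2)
  one <- kmeans_discretize(X, k = 1, seed = 1)
  expect_equal(one$centers[1, ], colMeans(X), tolerance = 1e-12)
  all_k <- kmeans_discretize(X, k = 10, seed = 1)
  expect_equal(all_k$inertia, 0, tolerance = 1e-20)
  expect_equal(sort(unique(all_k$labels)), 1:10)
  expect_error(kmeans_discretize(X, k = 11), "exceed")
})

test_that("k-means separates blobs and is competitive with a restart oracle", {
  set.seed(90)
  X <- rbind(matrix(stats::rnorm(200, 0, 0.3), ncol = 2),
             matrix(stats::rnorm(200, 6, 0.3), ncol = 2),
             matrix(cbind(stats::rnorm(100, 0, 0.3), stats::rnorm(100, 6, 0.3)), ncol = 2))
  fit <- kmeans_discretize(X, k = 3, seed = 42)
  truth <- rep(1:3, each = 100)
  expect_true(same_partition(fit$labels, truth))
  oracle <- stats::kmeans(X, 3, nstart = 20)
  expect_lt(fit$inertia, oracle$tot.withinss * 1.01)
  # determinism under a fixed seed
  expect_identical(fit$labels, kmeans_discretize(X, k = 3, seed = 42)$labels)
})

test_that("transition counting matches hand counts and a brute-force counter", {
  C <- count_transitions(c(1, 2, 1, 2, 1), lag = 1)
  expect_equal(C$counts, matrix(c(0, 2, 2, 0), 2, 2))
  C2 <- count_transitions(c(1, 1, 1, 1), lag = 2)
  expect_equal(C2$counts, matrix(2))
  set.seed(77)
  dtrajs <- lapply(1:4, function(i) sample.int(5, 60, replace = TRUE))
  for (lag in c(1, 3, 7)) {
    Cs <- count_transitions(dtrajs, lag, n_states = 5)$counts
    brute <- matrix(0, 5, 5)
    for (d in dtrajs) for (t in seq_len(length(d) - lag)) {
      brute[d[t], d[t + lag]] <- brute[d[t], d[t + lag]] + 1
    }
    expect_equal(Cs, brute)
  }
  # strided mode skips overlapping pairs
  Cst <- count_transitions(c(1, 2, 1, 2, 1), lag = 2, mode = "strided")
  expect_equal(sum(Cst$counts), 2)
  expect_error(count_transitions(c(1, 2), lag = 5), "shorter")
})

test_that("largest connected set matches a Kosaraju oracle and keeps the heavy block", {
  full <- matrix(5, 3, 3)
  lcs <- largest_connected_set(full)
  expect_equal(lcs$active_set, 1:3)
  expect_equal(lcs$fraction_retained, 1.0)
  blocks <- matrix(0, 4, 4)
  blocks[1:2, 1:2] <- 7; blocks[3:4, 3:4] <- 3
  lcs2 <- largest_connected_set(blocks)
  expect_equal(lcs2$active_set, 1:2)
  expect_equal(lcs2$fraction_retained, 0.7)
  set.seed(55)
  for (i in 1:10) {
    A <- matrix(stats::rpois(49, 0.4), 7, 7)
    lcs3 <- largest_connected_set(A)
    comp <- kosaraju_scc(A > 0)
    scores <- vapply(seq_len(max(comp)), function(cm) {
      m <- which(comp == cm); sum(A[m, m])
    }, numeric(1))
    best <- which(scores == max(scores))
    oracle_sets <- lapply(best, function(cm) sort(which(comp == cm)))
    expect_true(any(vapply(oracle_sets, identical, logical(1), y = lcs3$active_set)))
  }
})

test_that("reversible estimation reproduces the symmetric closed form", {
  m <- estimate_reversible_T(matrix(c(8, 2, 2, 8), 2, 2))
  expect_equal(m$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2), tolerance = 1e-8)
  expect_equal(m$stationary, c(0.5, 0.5), tolerance = 1e-8)
  db <- max(abs(m$stationary * m$T - t(m$stationary * m$T)))
  expect_lt(db, 1e-8)
})

test_that("a planted detailed-balance chain is recovered", {
  Ttrue <- matrix(c(0.94, 0.06, 0.02, 0.98), 2, 2, byrow = TRUE)
  pi_true <- stationary_distribution(Ttrue)
  expect_equal(pi_true, c(0.25, 0.75), tolerance = 1e-12)
  set.seed(101)
  s <- simulate_chain(Ttrue, 100000)
  m <- estimate_reversible_T(count_transitions(s, 1))
  expect_lt(max(abs(m$stationary - pi_true)), 0.02)
  expect_lt(max(abs(m$T - Ttrue)), 0.02)
})

test_that("the reversible estimate is a likelihood local optimum", {
  set.seed(33)
  C <- matrix(stats::rpois(16, 20) + 1, 4, 4)
  m <- estimate_reversible_T(C, tol = 1e-14)
  loglik <- function(T) sum(C * log(T))
  base <- loglik(m$T)
  X <- m$stationary * m$T  # symmetric flux matrix
  for (i in 1:20) {
    E <- matrix(stats::rnorm(16, sd = 1e-4), 4, 4)
    E <- (E + t(E)) / 2
    Xp <- X + E
    Xp[Xp <= 0] <- 1e-12
    Tp <- Xp / rowSums(Xp)
    expect_lte(loglik(Tp), base + 1e-9)
  }
})

test_that("non-connected input is refused", {
  blocks <- matrix(0, 4, 4)
  blocks[1:2, 1:2] <- 5; blocks[3:4, 3:4] <- 5
  expect_error(estimate_reversible_T(blocks, active = 1:4), "connected")
  # but the default trims to the largest block
  m <- estimate_reversible_T(blocks)
  expect_equal(nrow(m$T), 2)
  expect_equal(m$fraction_retained, 0.5)
})

test_that("implied timescales match the closed form and flag degeneracies", {
  T2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  m <- structure(list(T = T2, stationary = c(0.5, 0.5), lag = 10L,
                      lag_ns = 10, frame_dt = 1, active_set = 1:2,
                      fraction_retained = 1, counts = T2 * 100),
                 class = "ms_model")
  expect_equal(implied_timescales(m, 1), -10 / log(0.8), tolerance = 1e-12)
  expect_equal(signif(implied_timescales(m, 1), 4), 44.81)
  Tdisc <- diag(2)
  mdisc <- m; mdisc$T <- Tdisc
  expect_equal(implied_timescales(mdisc, 1), Inf)
  expect_error(implied_timescales(m, 2), "smaller")
})

test_that("3-state ground-truth timescales are recovered and lag-robust", {
  Ttrue <- matrix(c(0.96, 0.03, 0.01,
                    0.02, 0.96, 0.02,
                    0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  lam <- sort(Re(eigen(Ttrue)$values), decreasing = TRUE)
  truth <- -1 / log(lam[2])
  set.seed(202)
  dtrajs <- lapply(1:20, function(i) simulate_chain(Ttrue, 5000, start = sample(3, 1)))
  for (lag in c(5, 10, 20)) {
    m <- estimate_reversible_T(count_transitions(dtrajs, lag))
    ts <- implied_timescales(m, 1) # frame_dt = 1, so ns = frames
    expect_lt(abs(ts - truth) / truth, 0.10)
  }
})

test_that("Chapman-Kolmogorov is flat for Markovian data and not for lumped data", {
  Ttrue <- matrix(c(0.95, 0.04, 0.01,
                    0.04, 0.92, 0.04,
                    0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  set.seed(301)
  dtrajs <- lapply(1:10, function(i) simulate_chain(Ttrue, 10000, start = sample(3, 1)))
  m <- estimate_reversible_T(count_transitions(dtrajs, 1))
  ck <- ck_test(dtrajs, m, factors = 1:5)
  expect_equal(ck$max_abs_deviation[1], 0, tolerance = 1e-12)
  expect_lt(max(ck$max_abs_deviation), 0.03)
  # lump two kinetically distinct hidden states -> memory in the observed chain
  Thid <- matrix(c(0.90, 0.10, 0.00,
                   0.10, 0.80, 0.10,
                   0.00, 0.10, 0.90), 3, 3, byrow = TRUE)
  hid <- lapply(1:10, function(i) simulate_chain(Thid, 10000, start = sample(3, 1)))
  lumped <- lapply(hid, function(s) ifelse(s <= 2, 1L, 2L))
  ml <- estimate_reversible_T(count_transitions(lumped, 1))
  ckl <- ck_test(lumped, ml, factors = 2:5)
  expect_gt(max(ckl$max_abs_deviation), max(ck$max_abs_deviation))
})
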