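test_that("discretisation maps values to their bins", {
  s <- discretize(c(1, 2, 3), bin_edges = c(0, 1.5, 2.5, 3.5))
  expect_identical(as.integer(s), 1:3)
  # out-of-range values clamp to the edge bins
  s2 <- discretize(c(-5, 10), bin_edges = c(0, 1, 2))
  expect_identical(as.integer(s2), c(1L, 2L))
  expect_length(unique(as.integer(discretize(rep(2, 10), n_bins = 5))), 1)
  expect_error(discretize(1:3, n_bins = 1), "n_bins")
  expect_error(discretize(1:3, bin_edges = c(1, 1, 2)), "increasing")
})

test_that("bin refinement is consistent with coarse assignment", {
  set.seed(51)
  x <- runif(500, 0, 8)
  coarse <- discretize(x, bin_edges = seq(0, 8, by = 1))
  fine <- discretize(x, bin_edges = seq(0, 8, by = 0.5))
  expect_identical(as.integer(ceiling(fine / 2)), as.integer(coarse))
})

test_that("count matrices match hand counts and respect boundaries", {
  C <- count_matrix(c(1, 1, 2, 2, 1), lag = 1)
  expect_equal(C, matrix(c(1, 1, 1, 1), 2))
  expect_equal(sum(count_matrix(c(1, 1, 2, 2, 1), lag = 4)), 1)
  expect_error(count_matrix(c(1, 2), lag = 5), "shorter than the lag")
  # two trajectories vs their concatenation: brute-force pair enumeration
  s1 <- c(1, 2, 1, 1); s2 <- c(2, 2, 1, 2)
  sep <- count_matrix(list(s1, s2), lag = 1)
  brute <- matrix(0L, 2, 2)
  for (s in list(s1, s2))
    for (t in seq_len(length(s) - 1))
      brute[s[t], s[t + 1]] <- brute[s[t], s[t + 1]] + 1L
  expect_equal(sep, brute)
  concat <- count_matrix(c(s1, s2), lag = 1)
  expect_equal(sum(concat), sum(sep) + 1)  # one extra boundary pair
})

test_that("transition matrix estimation normalises and symmetrises", {
  C <- rbind(c(9, 1), c(5, 5))
  m <- transition_matrix(C, reversible = FALSE)
  expect_equal(m$transition_matrix, rbind(c(0.9, 0.1), c(0.5, 0.5)))
  expect_equal(rowSums(m$transition_matrix), c(1, 1))
  # symmetric counts: both estimators coincide
  S <- rbind(c(6, 2), c(2, 4))
  expect_equal(transition_matrix(S, reversible = TRUE)$transition_matrix,
               transition_matrix(S, reversible = FALSE)$transition_matrix)
})

test_that("reversible estimates satisfy detailed balance", {
  set.seed(52)
  for (rep in 1:10) {
    C <- matrix(rpois(16, 20), 4)
    m <- transition_matrix(C, reversible = TRUE)
    pi_ <- m$stationary
    T_ <- m$transition_matrix
    flux <- outer(pi_, rep(1, 4)) * T_
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    expect_lt(max(abs(pi_ %*% T_ - pi_)), 1e-10)
  }
})

test_that("disconnected states are trimmed to the largest strong component", {
  C <- rbind(c(10, 5, 0), c(5, 10, 0), c(0, 0, 7))
  m <- transition_matrix(C)
  expect_identical(m$active_set, 1:2)
  expect_identical(dim(m$transition_matrix), c(2L, 2L))
})

test_that("stationary distributions solve pi T = pi", {
  expect_equal(stationary_distribution(rbind(c(0.5, 0.5), c(0.5, 0.5))),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(rbind(c(0.9, 0.1), c(0.5, 0.5))),
               c(5 / 6, 1 / 6), tolerance = 1e-12)
  set.seed(53)
  for (rep in 1:100) {
    T_ <- random_stochastic(sample(2:6, 1))
    pi_ <- stationary_distribution(T_)
    expect_lt(max(abs(pi_ %*% T_ - pi_)), 1e-10)
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
    expect_true(all(pi_ >= 0))
  }
})

test_that("reducible chains error naming the blocks", {
  T_ <- rbind(c(1, 0), c(0, 1))
  expect_error(stationary_distribution(T_), "reducible")
})

test_that("implied timescales follow -lag / log(lambda)", {
  # two-state chain with p01 = p10 = 0.25: lambda2 = 0.5
  T_ <- rbind(c(0.75, 0.25), c(0.25, 0.75))
  ts <- implied_timescales(T_, lag = 1)
  expect_equal(ts, -1 / log(0.5), tolerance = 1e-12)
  expect_equal(round(ts, 4), 1.4427)
  # closed form for a general two-state chain
  p01 <- 0.02; p10 <- 0.07
  T2 <- rbind(c(1 - p01, p01), c(p10, 1 - p10))
  expect_equal(implied_timescales(T2, lag = 3),
               -3 / log(1 - p01 - p10), tolerance = 1e-12)
  # lambda -> 1 reports an infinite timescale
  T3 <- rbind(c(1 - 1e-16, 1e-16), c(1e-16, 1 - 1e-16))
  expect_true(is.infinite(implied_timescales(T3, lag = 1)))
})

test_that("free energies are -ln(pi) shifted to zero minimum", {
  fel <- reweighted_fel(c(0.8, 0.2), c(4.5, 7.5))
  expect_equal(fel$dG_kT, c(0, log(4)), tolerance = 1e-12)
  expect_equal(fel$dG_kcal, c(0, log(4)) * 0.0019872041 * 300)
  expect_equal(reweighted_fel(rep(0.25, 4), 1:4)$dG_kT, rep(0, 4))
  # zero-probability bins get +Inf and stay out of the minimum
  fel0 <- reweighted_fel(c(0.5, 0.5, 0), 1:3)
  expect_true(is.infinite(fel0$dG_kT[3]))
  expect_equal(min(fel0$dG_kT[1:2]), 0)
  # occupancy duality
  pi_ <- c(0.6, 0.3, 0.1)
  g <- reweighted_fel(pi_, 1:3)$dG_kT
  expect_equal(exp(-g) / sum(exp(-g)), pi_, tolerance = 1e-10)
})

test_that("estimated transition matrix converges to the true chain", {
  ts <- generate_two_state_series(c(0.01, 0.03), list(c(0, 0.1), c(1, 0.1)),
                                  n_frames = 1e6, seed = 54)
  C <- count_matrix(ts$hidden_states + 1L, lag = 1)
  m <- transition_matrix(C, reversible = FALSE)
  truth <- rbind(c(0.99, 0.01), c(0.03, 0.97))
  expect_lt(max(abs(m$transition_matrix - truth)), 0.01)
})

test_that("the MSM free-energy gap matches the stationary occupancies", {
  ts <- generate_two_state_series(c(0.01, 0.03),
                                  list(c(4.5, 0.3), c(7.5, 0.5)),
                                  n_frames = 1e5, seed = 55)
  msm <- build_msm(ts, n_bins = 30, lag = 1)
  fel <- msm$fel
  edges <- msm$model$bin_edges
  centers <- fel$center
  # free energy of each basin: -ln of summed occupancy on its side of 6 A
  pi_ <- msm$model$stationary
  occ_open <- sum(pi_[centers > 6])
  expect_equal(log(occ_open / (1 - occ_open)), log(0.25 / 0.75),
               tolerance = 0.15)
  # the global FEL minimum lies in the closed (majority) basin
  expect_lt(centers[which.min(fel$dG_kT)], 6)
})

test_that("on open-dominant gating data the FEL minimum is the open state", {
  # mirror case: open (larger distance) state is the majority state
  ts <- generate_two_state_series(c(0.03, 0.01),
                                  list(c(4.5, 0.3), c(7.5, 0.5)),
                                  n_frames = 5e4, seed = 56)
  msm <- build_msm(ts, n_bins = 30, lag = 1)
  expect_gt(msm$fel$center[which.min(msm$fel$dG_kT)], 6)
})

test_that("automatic lag selection settles where timescales plateau", {
  ts <- generate_two_state_series(c(0.01, 0.03), list(c(0, 0.05), c(1, 0.05)),
                                  n_frames = 2e5, seed = 57)
  msm <- build_msm(ts, n_bins = 10)
  expect_gte(msm$model$lag, 1L)
  # Markovian input: timescale at the chosen lag matches the closed form
  expect_equal(msm$timescales[1], -msm$model$lag / log(1 - 0.04),
               tolerance = 0.1 * abs(-msm$model$lag / log(1 - 0.04)))
})
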