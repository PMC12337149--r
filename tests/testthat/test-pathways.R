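make_two_tunnels <- function() {
  list(new_tunnel("T1", rbind(c(0, 0, 5), c(0, 0, 10), c(0, 0, 15)),
                  c(2, 2, 2)),
       new_tunnel("T2", rbind(c(5, 0, 0), c(10, 0, 0), c(15, 0, 0)),
                  c(2, 2, 2)))
}

test_that("tunnel files round-trip through the sphere-record dialect", {
  tun <- list(new_tunnel("T1", rbind(c(1.25, -2.5, 3), c(4, 5.125, -6)),
                         c(1.25, 2.75)),
              new_tunnel("T2", rbind(c(7, 8, 9), c(10, 11, 12), c(0, 0, 1)),
                         c(0.5, 0.75, 3)))
  f <- tempfile(fileext = ".pdb")
  write_tunnels(tun, f)
  back <- load_tunnels(f)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$id, tun[[i]]$id)
    expect_equal(back[[i]]$centers, tun[[i]]$centers)
    expect_equal(back[[i]]$radii, tun[[i]]$radii)
  }
})

test_that("spheres listed surface-first are reordered site-first", {
  tun <- list(new_tunnel("T1", rbind(c(0, 0, 15), c(0, 0, 10), c(0, 0, 5)),
                         c(3, 2, 1)))
  f <- tempfile(fileext = ".pdb")
  write_tunnels(tun, f)
  back <- load_tunnels(f, site_anchor = c(0, 0, 0))
  expect_equal(back[[1]]$centers[, 3], c(5, 10, 15))
  expect_equal(back[[1]]$radii, c(1, 2, 3))
})

test_that("malformed sphere records are reported with their line number", {
  f <- tempfile(fileext = ".pdb")
  write_tunnels(list(new_tunnel("T1", rbind(c(1, 2, 3), c(4, 5, 6)),
                                c(1.5, 1.5))), f)
  lines <- readLines(f)
  # corrupt the y field of the second sphere record
  substr(lines[2], 39, 46) <- "   xxxxx"
  writeLines(lines, f)
  expect_error(load_tunnels(f), "line 2")
  expect_error(load_tunnels(tempfile()), "not found")
})

test_that("traces on tunnel centres assign exactly, ties to the first id", {
  tun <- make_two_tunnels()
  expect_identical(assign_event(tun[[1]]$centers, tun), "T1")
  expect_identical(assign_event(tun[[2]]$centers, tun), "T2")
  # equidistant single point between T1 and T2
  p <- matrix(c(5 / sqrt(2), 0, 5 / sqrt(2)), 1)
  expect_identical(assign_event(p, tun), "T1")
  far <- matrix(c(100, 100, 100), 1)
  expect_identical(assign_event(far, tun, max_assign_dist = 5),
                   "unassigned")
  expect_error(assign_event(p, list()), "empty tunnel list")
})

test_that("assignment is rigid-motion equivariant", {
  tun <- make_two_tunnels()
  set.seed(17)
  trace <- tun[[2]]$centers + matrix(rnorm(9, 0, 0.5), 3)
  # random rotation (QR of a Gaussian matrix) plus translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(12, -3, 7)
  rot <- function(m) sweep(m %*% t(R), 2, shift, "+")
  tun_rot <- lapply(tun, function(t)
    new_tunnel(t$id, rot(t$centers), t$radii))
  expect_identical(assign_event(trace, tun),
                   assign_event(rot(trace), tun_rot))
})

test_that("pathway distributions are normalised with bootstrap errors", {
  pd <- pathway_distribution(c("T1", "T1", "T1", "T2"), n_boot = 200,
                             seed = 5)
  expect_equal(pd$probability, c(0.75, 0.25))
  expect_equal(sum(pd$probability), 1)
  expect_equal(sum(pd$count), attr(pd, "n_events"))
  expect_true(all(pd$se >= 0))
  one <- pathway_distribution(rep("T3", 8), n_boot = 100, seed = 1)
  expect_equal(one$probability, 1)
  expect_equal(one$se, 0)
})

test_that("chi-square is zero for identical tables and matches the oracle", {
  a <- c(T1 = 10, T2 = 10, T3 = 10)
  res <- chi_square_compare(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # 2x2 hand-computed table: expected counts all 15, chi2 = 4*25/15
  res2 <- chi_square_compare(c(x = 20, y = 10), c(x = 10, y = 20))
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(res2$degrees_of_freedom, 1L)
  # independent oracle: stats::chisq.test without continuity correction
  oracle <- stats::chisq.test(rbind(c(20, 10), c(10, 20)), correct = FALSE)
  expect_equal(res2$statistic, unname(oracle$statistic))
  expect_equal(res2$p_value, oracle$p.value)
  expect_equal(round(res2$p_value, 4), 0.0098)
})

test_that("chi-square is invariant under category permutation", {
  a <- c(T1 = 25, T2 = 5, T3 = 12, T4 = 8)
  b <- c(T1 = 14, T2 = 9, T3 = 15, T4 = 12)
  r1 <- chi_square_compare(a, b)
  perm <- c(3, 1, 4, 2)
  r2 <- chi_square_compare(a[perm], b[perm])
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Monte-Carlo p-values agree with the resampling oracle", {
  a <- c(x = 20, y = 10); b <- c(x = 10, y = 20)
  mc <- chi_square_compare(a, b, min_expected = 30, mc_replicates = 2e4,
                           seed = 77)
  expect_identical(mc$method, "monte_carlo")
  # independent conditional-resampling oracle at matched replicate count
  set.seed(177)
  oracle <- stats::chisq.test(rbind(a, b), simulate.p.value = TRUE,
                              B = 2e4)
  mc_sd <- sqrt(mc$p_value * (1 - mc$p_value) / 2e4)
  expect_lt(abs(mc$p_value - oracle$p.value), 4 * sqrt(2) * mc_sd + 1e-4)
  # on a well-populated table the conditional and asymptotic p agree up
  # to the chi-square approximation bias
  a2 <- c(x = 45, y = 35, z = 40); b2 <- c(x = 35, y = 45, z = 40)
  asym2 <- chi_square_compare(a2, b2)
  mc2 <- chi_square_compare(a2, b2, min_expected = 50,
                            mc_replicates = 2e4, seed = 78)
  expect_lt(abs(mc2$p_value - asym2$p_value), 0.05)
})

test_that("sparse categories are pooled into 'other'", {
  a <- c(T1 = 30, T2 = 25, T3 = 2, T4 = 1)
  b <- c(T1 = 28, T2 = 24, T3 = 1, T4 = 2)
  res <- chi_square_compare(a, b)
  expect_true("other" %in% res$pooled_categories)
  expect_identical(length(res$pooled_categories), 3L)
  expect_identical(res$degrees_of_freedom, 2L)
})

test_that("merge maps are honoured before testing", {
  a <- c(T1 = 20, T2 = 15, T3 = 10)
  b <- c(T1 = 18, T2 = 17, T3 = 10)
  merged <- chi_square_compare(a, b, merge_map = c(T1 = "T1+T2",
                                                   T2 = "T1+T2"))
  direct <- chi_square_compare(c(`T1+T2` = 35, T3 = 10),
                               c(`T1+T2` = 35, T3 = 10))
  expect_identical(length(merged$pooled_categories), 2L)
  expect_equal(direct$statistic, 0)
  expect_error(chi_square_compare(a, b[1:2]), "identical categories")
})

test_that("toy-system assignments reproduce the recorded channels", {
  sys <- toy_system()
  tun <- toy_tunnels(sys)
  traj <- simulate_ligand_diffusion(sys, 9, 8000, seed = 301)
  ev <- extract_events(label_frames(traj))
  asg <- assign_events(ev, tun)
  expect_identical(asg, paste0("T", traj$events$channel))
  pd <- pathway_distribution(asg, n_boot = 100, seed = 1,
                             categories = c("T1", "T2", "T3", "unassigned"))
  gt <- as.integer(table(factor(paste0("T", traj$events$channel),
                                c("T1", "T2", "T3", "unassigned"))))
  expect_identical(pd$count, gt)
})
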