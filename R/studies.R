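#' Synthetic k_on recovery and pathway-symmetry study
#'
#' Runs the full analysis pipeline on many independently seeded toy
#' systems and compares the recovered kinetics and pathway usage against
#' the generator's recorded ground truth. The ground-truth association
#' rate is estimated from additional independent calibration runs of the
#' same protocol (copy number and length), so rebinding and run-length
#' censoring affect the truth and the estimates identically.
#'
#' Per run the study records the k_on estimate with its bootstrap
#' confidence interval, whether every event's recovered tunnel matches the
#' recorded channel, and the chi-square comparison of binding vs unbinding
#' pathway counts (detailed balance predicts symmetry).
#'
#' @param n_runs number of independent pipeline runs, default 50.
#' @param n_ligands ligand copies per run, default 16.
#' @param n_frames frames per run, default 15000 (75 ns at the default
#'   timestep).
#' @param calib_runs,calib_ligands calibration runs for the ground-truth
#'   rate, default 24 runs at the same copy number and length as the
#'   study runs, so the truth is the large-sample limit of the identical
#'   protocol (same rebinding and censoring characteristics) and its own
#'   sampling error stays well below the per-run interval width.
#' @param system the [toy_system()]; defaults to the standard geometry.
#' @param n_boot bootstrap replicates per run, default 500.
#' @param mc_replicates Monte-Carlo chi-square replicates, default 2e4.
#' @param seed master seed; every run seed derives from it.
#' @param level confidence level for the k_on interval, default 0.95.
#' @param quiet suppress per-run progress messages.
#' @return list with `kon_true` (calibration rate), `concentration`,
#'   `runs` (data.frame: kon, lo, hi, covered, n_binding, n_events,
#'   match_all, match_rate, p_symmetry), `pooled_counts` (recovered per
#'   tunnel), `gt_counts` (recorded per channel), and
#'   `calib_channel_probs`.
#' @export
kon_recovery_study <- function(n_runs = 50, n_ligands = 16,
                               n_frames = 15000, calib_runs = 24,
                               calib_ligands = n_ligands,
                               system = toy_system(),
                               n_boot = 500, mc_replicates = 2e4,
                               seed = 1, level = 0.95, quiet = TRUE) {
  tunnels <- toy_tunnels(system)
  cats <- c(vapply(tunnels, `[[`, character(1), "id"), "unassigned")
  conc <- ligand_concentration(n_ligands, system$box_edge^3)
  conc_cal <- ligand_concentration(calib_ligands, system$box_edge^3)
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_runs + calib_runs))

  # ground-truth rate from the calibration ensemble
  calib_fpts <- numeric(0)
  calib_channels <- integer(0)
  for (k in seq_len(calib_runs)) {
    traj <- simulate_ligand_diffusion(system, calib_ligands, n_frames,
                                      seed = seeds[n_runs + k])
    ev <- extract_events(label_frames(traj))
    calib_fpts <- c(calib_fpts, site_fpts(ev))
    calib_channels <- c(calib_channels,
                        traj$events$channel[traj$events$type == "binding"])
  }
  kon_true <- 1 / (mean(calib_fpts) * 1e-9 * conc_cal)

  runs <- vector("list", n_runs)
  pooled <- stats::setNames(rep(0L, length(cats)), cats)
  gt_pool <- stats::setNames(rep(0L, length(tunnels)),
                             vapply(tunnels, `[[`, character(1), "id"))
  for (i in seq_len(n_runs)) {
    s <- seeds[i]
    traj <- simulate_ligand_diffusion(system, n_ligands, n_frames, seed = s)
    ev <- extract_events(label_frames(traj))
    fpts <- site_fpts(ev)
    est <- estimate_kon(fpts, conc, n_boot = n_boot, seed = s + 1L)
    ci <- confint(est, level = level)
    asg <- suppressWarnings(assign_events(ev, tunnels))
    gt <- paste0("T", traj$events$channel)
    ok <- !is.na(asg)
    match_rate <- mean(asg[ok] == gt[ok])
    tab <- table(factor(asg[ok], cats))
    pooled <- pooled + as.integer(tab)
    gtb <- table(factor(gt, names(gt_pool)))
    gt_pool <- gt_pool + as.integer(gtb)
    ca <- table(factor(asg[ok & ev$type == "binding"], cats))
    cb <- table(factor(asg[ok & ev$type == "unbinding"], cats))
    sym <- chi_square_compare(stats::setNames(as.integer(ca), cats),
                              stats::setNames(as.integer(cb), cats),
                              mc_replicates = mc_replicates,
                              seed = s + 2L)
    runs[[i]] <- data.frame(
      kon = est$rate, lo = ci[1, 1], hi = ci[1, 2],
      covered = ci[1, 1] <= kon_true && kon_true <= ci[1, 2],
      n_binding = length(fpts), n_events = nrow(ev),
      match_all = all(asg[ok] == gt[ok]), match_rate = match_rate,
      p_symmetry = sym$p_value)
    if (!quiet)
      message(sprintf("run %d/%d: k_on %.3g [%.3g, %.3g], p_sym %.3f",
                      i, n_runs, est$rate, ci[1, 1], ci[1, 2],
                      sym$p_value))
  }
  list(kon_true = kon_true, concentration = conc,
       runs = do.call(rbind, runs), pooled_counts = pooled,
       gt_counts = gt_pool,
       calib_channel_probs = as.numeric(table(factor(calib_channels,
         seq_along(tunnels)))) / length(calib_channels))
}

#' Chi-square type-I error calibration study
#'
#' Draws pairs of count vectors from one shared multinomial and records
#' how often [chi_square_compare()] rejects at the given alpha; a
#' calibrated test rejects at close to the nominal rate.
#'
#' @param n_rep number of repetitions, default 2000.
#' @param n per-sample total count, default 80.
#' @param k number of categories, default 6.
#' @param probs category probabilities, default uniform.
#' @param alpha nominal level, default 0.05.
#' @param mc_replicates Monte-Carlo replicates for sparse draws.
#' @param seed master seed.
#' @return list with `reject_rate` and `n_rep`.
#' @export
chi_square_type1_study <- function(n_rep = 2000, n = 80, k = 6,
                                   probs = rep(1 / k, k), alpha = 0.05,
                                   mc_replicates = 2000, seed = 1) {
  cats <- paste0("c", seq_len(k))
  rej <- with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      a <- stats::setNames(as.integer(stats::rmultinom(1, n, probs)), cats)
      b <- stats::setNames(as.integer(stats::rmultinom(1, n, probs)), cats)
      p <- chi_square_compare(a, b, mc_replicates = mc_replicates,
                              seed = r)$p_value
      p < alpha
    }, logical(1))
  })
  list(reject_rate = mean(rej), n_rep = n_rep)
}
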