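#' Ligand concentration from copy number and box volume
#'
#' C = N / (N_A * V), with the nm^3 -> L conversion (1 nm^3 = 1e-24 L).
#'
#' @param n_ligands number of ligand copies in the box.
#' @param box_volume box volume (nm^3).
#' @return concentration in mol/L.
#' @export
#' @examples
#' ligand_concentration(100, 1387.3)   # ~0.1197 M
ligand_concentration <- function(n_ligands, box_volume) {
  if (n_ligands < 1) stopf("n_ligands must be >= 1")
  check_positive(box_volume, "box_volume")
  n_ligands / (.AVOGADRO * box_volume * 1e-24)
}

.new_kinetics_estimate <- function(rate, se, n, mean_passage,
                                   concentration = NA_real_, kind) {
  structure(list(rate = rate, standard_error = se, n_events = n,
                 mean_passage = mean_passage, concentration = concentration,
                 kind = kind),
            class = "kinetics_estimate")
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  unit <- if (x$kind == "kon") "M^-1 s^-1" else "s^-1"
  cat(sprintf("%s = %.3g +/- %.2g %s  (n = %d events, mean passage %.3g ns)\n",
              x$kind, x$rate, x$standard_error, unit, x$n_events,
              x$mean_passage))
  invisible(x)
}

.boot_rate <- function(x, stat, n_boot, seed) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b)
      stat(sample(x, length(x), replace = TRUE)), numeric(1))
    stats::sd(reps)
  })
}

#' Site-level first-passage times from an event table
#'
#' Merges the events of all ligand copies of each replica chronologically
#' and returns the waiting times of the binding site: the time from
#' replica start (or from the moment the site last became free after an
#' unbinding) until the next binding. These are the first-passage times
#' that enter `k_on = 1 / (mean(FPT) * C)`; unlike per-ligand diffusion
#' times they are invariant under the number of ligand copies, because a
#' higher copy number shortens the waiting time in exact proportion to
#' the concentration.
#'
#' @param events an [event_table][extract_events] whose `replica` column
#'   groups ligand copies simulated together.
#' @return numeric vector of first-passage times (ns), one per site-level
#'   binding; bindings completing on the same frame as the preceding
#'   unbinding carry no measurable waiting time and are dropped.
#' @export
site_fpts <- function(events) {
  out <- numeric(0)
  for (rep_id in unique(events$replica)) {
    e <- events[events$replica == rep_id, , drop = FALSE]
    e <- e[order(e$end_time), , drop = FALSE]
    occ <- 0L; t_ref <- 0
    for (i in seq_len(nrow(e))) {
      if (e$type[i] == "binding") {
        if (occ == 0L) out <- c(out, e$end_time[i] - t_ref)
        occ <- occ + 1L
      } else {
        occ <- max(0L, occ - 1L)
        if (occ == 0L) t_ref <- e$end_time[i]
      }
    }
  }
  out[out > 0]
}

#' Association rate constant from first-passage times
#'
#' k_on = 1 / (mean(FPT) * C), converting ns to s. The standard error is
#' the standard deviation of k_on over bootstrap resamples of the event
#' list (resampling unit = event).
#'
#' @param fpts first-passage times (ns), one per binding event.
#' @param concentration ligand concentration (mol/L).
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return a `kinetics_estimate` (rate in 1/(M s)).
#' @export
#' @examples
#' estimate_kon(c(89.6, 89.6), 0.1197, n_boot = 100, seed = 1)$rate  # 9.3e7
estimate_kon <- function(fpts, concentration, n_boot = 1000, seed = NULL) {
  if (length(fpts) == 0) stopf("no events: cannot estimate k_on")
  check_positive(concentration, "concentration")
  if (any(fpts <= 0)) stopf("first-passage times must be > 0")
  kon_of <- function(v) 1 / (mean(v) * 1e-9 * concentration)
  se <- if (length(fpts) == 1) 0
        else .boot_rate(fpts, kon_of, n_boot, seed)
  .new_kinetics_estimate(kon_of(fpts), se, length(fpts), mean(fpts),
                         concentration, kind = "kon")
}

#' Dissociation rate constant from residence times
#'
#' k_off = 1 / mean(residence time), converting ns to s; bootstrap SE over
#' events as in [estimate_kon()].
#'
#' @param residence_times residence times (ns), one per unbinding event.
#' @inheritParams estimate_kon
#' @return a `kinetics_estimate` (rate in 1/s).
#' @export
#' @examples
#' estimate_koff(c(4, 5, 4.5, 4.5), n_boot = 100, seed = 1)$rate  # 2.22e8
estimate_koff <- function(residence_times, n_boot = 1000, seed = NULL) {
  if (length(residence_times) == 0) stopf("no events: cannot estimate k_off")
  if (any(residence_times <= 0)) stopf("residence times must be > 0")
  koff_of <- function(v) 1 / (mean(v) * 1e-9)
  se <- if (length(residence_times) == 1) 0
        else .boot_rate(residence_times, koff_of, n_boot, seed)
  .new_kinetics_estimate(koff_of(residence_times), se,
                         length(residence_times), mean(residence_times),
                         kind = "koff")
}

#' Experimental reference k_on from Michaelis-Menten constants
#'
#' Uses the catalytic efficiency k_cat / K_m as the association rate
#' estimate, the standard approximation when binding is rate-limiting. The
#' conversion formula is configurable via `formula`.
#'
#' @param K_m Michaelis constant (mol/L).
#' @param k_cat catalytic constant (1/s).
#' @param formula function of `(K_m, k_cat)` returning 1/(M s); defaults to
#'   `k_cat / K_m`.
#' @return k_on in 1/(M s).
#' @export
experimental_kon <- function(K_m, k_cat,
                             formula = function(K_m, k_cat) k_cat / K_m) {
  check_positive(K_m, "K_m")
  check_positive(k_cat, "k_cat")
  formula(K_m, k_cat)
}

#' Confidence interval for a kinetics estimate
#'
#' Normal-theory interval `rate +/- z * SE` built from the bootstrap
#' standard error, matching the rate +/- SE form in which such estimates
#' are reported. For a percentile interval use [bootstrap_rate_ci()].
#'
#' @param object a `kinetics_estimate`.
#' @param parm ignored (single parameter).
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return 1 x 2 matrix with lower and upper bounds.
#' @export
confint.kinetics_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$rate - z * object$standard_error,
                  object$rate + z * object$standard_error), 1, 2)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  rownames(out) <- object$kind
  out
}

#' Bootstrap percentile confidence interval for a rate
#'
#' @param x passage times (ns).
#' @param stat function mapping a resampled vector to the rate.
#' @param level confidence level, default 0.95.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return length-2 vector (lower, upper).
#' @export
bootstrap_rate_ci <- function(x, stat, level = 0.95, n_boot = 1000,
                              seed = NULL) {
  if (length(x) == 0) stopf("no events")
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b)
      stat(sample(x, length(x), replace = TRUE)), numeric(1))
    unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}
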