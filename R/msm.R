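#' Discretize a continuous series onto bins
#'
#' Maps each frame to its bin index; values outside the edge range go to
#' the nearest edge bin.
#'
#' @param series numeric vector, `bottleneck_series`, `two_state_series`,
#'   or a list of any of these (one element per trajectory).
#' @param bin_edges strictly increasing numeric vector of bin boundaries;
#'   give either this or `n_bins`.
#' @param n_bins number of equal-width bins over the observed range,
#'   default 40.
#' @return integer vector of 1-based states (or a list of them), with the
#'   edges used in attribute `bin_edges`.
#' @export
discretize <- function(series, bin_edges = NULL, n_bins = 40) {
  if (is.list(series) && !inherits(series, c("bottleneck_series",
                                             "two_state_series"))) {
    vals <- lapply(series, .series_values)
    if (is.null(bin_edges)) {
      rng <- range(unlist(vals))
      if (n_bins < 2) stopf("n_bins must be >= 2")
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    }
    out <- lapply(vals, .discretize_one, edges = bin_edges)
    attr(out, "bin_edges") <- bin_edges
    return(out)
  }
  x <- .series_values(series)
  if (is.null(bin_edges)) {
    if (n_bins < 2) stopf("n_bins must be >= 2")
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant series
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  if (any(diff(bin_edges) <= 0))
    stopf("bin_edges must be strictly increasing")
  s <- .discretize_one(x, bin_edges)
  attr(s, "bin_edges") <- bin_edges
  s
}

.discretize_one <- function(x, edges) {
  k <- length(edges) - 1L
  s <- findInterval(x, edges, rightmost.closed = TRUE)
  s[s < 1L] <- 1L
  s[s > k] <- k
  as.integer(s)
}

#' Transition count matrix at a lag time
#'
#' C[i, j] = number of frame pairs (t, t + lag) in states (i, j), summed
#' over trajectories with a sliding window; pairs never span trajectory
#' boundaries.
#'
#' @param sequences integer state sequence or list of them (1-based).
#' @param lag lag in frames, >= 1.
#' @param n_states matrix dimension; defaults to the largest observed
#'   state.
#' @return integer k x k matrix.
#' @export
count_matrix <- function(sequences, lag, n_states = NULL) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (lag < 1) stopf("lag must be >= 1")
  if (all(lengths(sequences) <= lag))
    stopf("all sequences are shorter than the lag (%d)", lag)
  if (is.null(n_states)) n_states <- max(unlist(sequences))
  C <- matrix(0L, n_states, n_states)
  for (s in sequences) {
    n <- length(s)
    if (n <= lag) next
    from <- s[1:(n - lag)]; to <- s[(1 + lag):n]
    tab <- table(factor(from, 1:n_states), factor(to, 1:n_states))
    C <- C + matrix(as.integer(tab), n_states, n_states)
  }
  C
}

#' Transition matrix estimate from counts
#'
#' Restricts to the largest strongly connected set of states, optionally
#' symmetrises the counts ((C + t(C)) / 2) for a detailed-balance
#' (reversible) estimate consistent with equilibrium sampling, adds an
#' optional pseudocount, and row-normalises.
#'
#' @param counts k x k count matrix.
#' @param reversible symmetrise before normalisation, default TRUE.
#' @param pseudocount added to every retained cell before normalisation,
#'   default 0.
#' @return object of class `markov_model`: list with `count_matrix`
#'   (restricted), `transition_matrix`, `stationary`, `active_set`
#'   (original state indices retained), `reversible`.
#' @export
transition_matrix <- function(counts, reversible = TRUE, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # largest strongly connected set; ties broken by total counts
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    tot <- vapply(best, function(b) {
      i <- which(comp$membership == b); sum(counts[i, i])
    }, numeric(1))
    best <- best[which.max(tot)]
  }
  active <- which(comp$membership == best)
  if (sum(counts[active, active]) == 0)
    stopf("empty connected set: no transitions among active states")
  C <- counts[active, active, drop = FALSE]
  S <- if (reversible) (C + t(C)) / 2 else C
  S <- S + pseudocount
  T_ <- S / rowSums(S)
  pi_ <- if (reversible) rowSums(S) / sum(S) else stationary_distribution(T_)
  structure(list(count_matrix = C, transition_matrix = T_,
                 stationary = pi_, active_set = active,
                 reversible = reversible),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d active states (%s), %d counts\n",
              length(x$active_set),
              if (x$reversible) "reversible" else "non-reversible",
              sum(x$count_matrix)))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The left eigenvector for eigenvalue one, normalised to sum one. Errors
#' if the chain is reducible, naming the disconnected blocks.
#'
#' @param T_ row-stochastic k x k matrix, irreducible.
#' @return probability vector of length k.
#' @export
#' @examples
#' stationary_distribution(rbind(c(0.9, 0.1), c(0.5, 0.5)))  # (5/6, 1/6)
stationary_distribution <- function(T_) {
  T_ <- as.matrix(T_)
  if (any(abs(rowSums(T_) - 1) > 1e-8))
    stopf("matrix rows must sum to 1")
  g <- igraph::graph_from_adjacency_matrix((T_ > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1) {
    blocks <- split(seq_len(nrow(T_)), comp$membership)
    stopf("transition matrix is reducible; strongly connected blocks: %s",
          paste(vapply(blocks, function(b)
            paste0("{", paste(b, collapse = ","), "}"), character(1)),
            collapse = " "))
  }
  e <- eigen(t(T_))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  v[abs(v) < 1e-14] <- 0
  if (any(v < 0)) stopf("stationary distribution has negative entries")
  v
}

#' Implied relaxation timescales of a transition matrix
#'
#' t_i = -lag / log(lambda_i) for eigenvalues sorted by decreasing
#' modulus, excluding the stationary eigenvalue 1. Eigenvalues with a
#' non-negligible imaginary part trigger a warning and their real part is
#' used; non-positive eigenvalues yield `NA` (no timescale
#' interpretation).
#'
#' @param T_ row-stochastic matrix.
#' @param lag lag time (frames or ns; the timescales inherit the unit).
#' @param im_tol tolerance on imaginary parts, default 1e-8.
#' @return numeric vector of timescales (length k - 1), `Inf` where
#'   lambda = 1 within machine tolerance.
#' @export
implied_timescales <- function(T_, lag, im_tol = 1e-8) {
  check_positive(lag, "lag")
  ev <- eigen(as.matrix(T_), only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  ev <- ev[-1]
  if (any(abs(Im(ev)) > im_tol))
    warning("complex eigenvalues beyond tolerance; using real parts",
            call. = FALSE)
  lam <- Re(ev)
  ts <- rep(NA_real_, length(lam))   # non-positive eigenvalues stay NA
  ts[lam >= 1 - 1e-12] <- Inf
  ok <- lam > 0 & lam < 1 - 1e-12
  ts[ok] <- -lag / log(lam[ok])
  ts
}

#' Stationary-reweighted free-energy landscape
#'
#' Delta G_i = -kB T ln(pi_i), shifted so the minimum is zero; reported in
#' kT and kcal/mol. Zero-probability bins get +Inf and are excluded from
#' the minimum.
#'
#' @param pi_ stationary probabilities over bins.
#' @param bin_centers coordinate of each bin (Angstrom).
#' @param temperature kelvin, default 300 (for the kcal/mol scale).
#' @return object of class `free_energy_landscape`: data.frame with
#'   columns center, dG_kT, dG_kcal; attribute `temperature`.
#' @export
#' @examples
#' reweighted_fel(c(0.8, 0.2), c(4.5, 7.5))$dG_kT  # (0, log(4))
reweighted_fel <- function(pi_, bin_centers, temperature = 300) {
  if (length(pi_) != length(bin_centers))
    stopf("pi_ and bin_centers must have equal length")
  if (any(pi_ < 0) || abs(sum(pi_) - 1) > 1e-6)
    stopf("pi_ must be a probability vector")
  check_positive(temperature, "temperature")
  g <- ifelse(pi_ > 0, -log(pi_), Inf)
  g <- g - min(g[is.finite(g)])
  kbt_kcal <- 0.0019872041 * temperature
  out <- data.frame(center = bin_centers, dG_kT = g,
                    dG_kcal = g * kbt_kcal)
  attr(out, "temperature") <- temperature
  class(out) <- c("free_energy_landscape", "data.frame")
  out
}

#' Build a Markov state model and free-energy landscape from series
#'
#' Convenience wrapper: discretize, count at a lag, estimate the
#' (reversible by default) transition matrix, and compute the stationary
#' distribution and free-energy landscape. When `lag` is `NULL` it is
#' chosen automatically as the smallest lag (from `1, 2, 4, ...`) whose
#' slowest implied timescale changes by less than 10 percent when the lag
#' doubles.
#'
#' @param series series or list of series (see [discretize()]).
#' @param n_bins number of bins, default 40.
#' @param lag lag in frames, or `NULL` for automatic selection.
#' @param reversible passed to [transition_matrix()].
#' @param temperature kelvin for the kcal/mol scale.
#' @param dt frame spacing (ns) used to report the lag in time units.
#' @return list with `model` (a `markov_model` plus `bin_edges`, `lag`),
#'   `fel` (a `free_energy_landscape`), `timescales`.
#' @export
build_msm <- function(series, n_bins = 40, lag = NULL, reversible = TRUE,
                      temperature = 300, dt = 1) {
  s <- discretize(series, n_bins = n_bins)
  edges <- attr(s, "bin_edges")
  seqs <- if (is.list(s)) s else list(s)
  max_lag <- max(2L, floor(max(lengths(seqs)) / 10))
  if (is.null(lag)) {
    lag <- 1L
    t_prev <- .t2_at(seqs, lag, reversible)
    while (2L * lag <= max_lag) {
      t_next <- .t2_at(seqs, 2L * lag, reversible)
      if (is.finite(t_prev) && is.finite(t_next) &&
          abs(t_next - t_prev) < 0.1 * t_prev) break
      lag <- 2L * lag
      t_prev <- t_next
    }
  }
  C <- count_matrix(seqs, lag, n_states = length(edges) - 1L)
  m <- transition_matrix(C, reversible = reversible)
  m$lag <- lag
  m$lag_ns <- lag * dt
  m$bin_edges <- edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  fel <- reweighted_fel(m$stationary, centers[m$active_set],
                        temperature = temperature)
  ts <- implied_timescales(m$transition_matrix, lag)
  list(model = m, fel = fel, timescales = ts)
}

.t2_at <- function(seqs, lag, reversible) {
  if (all(lengths(seqs) <= lag)) return(NA_real_)
  C <- count_matrix(seqs, lag)
  m <- tryCatch(transition_matrix(C, reversible = reversible),
                error = function(e) NULL)
  if (is.null(m)) return(NA_real_)
  ts <- suppressWarnings(implied_timescales(m$transition_matrix, lag))
  if (length(ts) == 0) NA_real_ else ts[1]
}
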