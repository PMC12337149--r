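#' Define a toy gas-binding system
#'
#' A minimal geometric stand-in for a buried-site enzyme in a periodic box:
#' a spherical protein exclusion volume pierced by a small number of
#' cylindrical channels that lead from the surface to a buried spherical
#' binding site. Gas ligands diffuse by overdamped Brownian motion and can
#' reach the site only through the channels, so channel-usage probabilities
#' are fixed by geometry and first-binding times are approximately
#' exponential.
#'
#' Internal units are nm and ns throughout.
#'
#' @param box_edge cubic box edge length (nm).
#' @param protein_center centre of the protein sphere (nm); defaults to the
#'   box centre.
#' @param protein_radius radius of the protein exclusion sphere (nm).
#' @param channels list of channels, each `list(axis = <unit 3-vector>,
#'   radius = <nm>)`. Axes are normalised on input.
#' @param site_radius radius of the buried binding-site sphere (nm). The
#'   default 0.5 nm mirrors the 5 Angstrom bound-state cutoff used for real
#'   trajectories.
#' @param diffusion_coeff ligand diffusion coefficient (nm^2/ns); the default
#'   4.5 is representative of H2 in water at room temperature.
#' @param timestep integration timestep (ns).
#' @param contact_cutoff bulk cutoff (nm): a ligand farther than
#'   `protein_radius + contact_cutoff` from the protein centre is in bulk
#'   ("unbound"); 0.4 nm mirrors the 4 Angstrom atom-contact criterion.
#'
#' @return an object of class `toy_system`.
#' @export
#' @examples
#' sys <- toy_system()
#' sys$channels
toy_system <- function(box_edge = 5,
                       protein_center = NULL,
                       protein_radius = 1.2,
                       channels = list(
                         list(axis = c(0, 0, 1),  radius = 0.45),
                         list(axis = c(1, 0, 0),  radius = 0.45),
                         list(axis = c(0, -1, 0), radius = 0.35)
                       ),
                       site_radius = 0.5,
                       diffusion_coeff = 4.5,
                       timestep = 0.005,
                       contact_cutoff = 0.4) {
  check_positive(box_edge, "box_edge")
  check_positive(protein_radius, "protein_radius")
  check_positive(site_radius, "site_radius")
  check_positive(diffusion_coeff, "diffusion_coeff")
  check_positive(timestep, "timestep")
  check_positive(contact_cutoff, "contact_cutoff")
  if (is.null(protein_center)) protein_center <- rep(box_edge / 2, 3)
  if (protein_radius >= box_edge / 2)
    stopf("protein_radius must be < box_edge/2")
  if (site_radius >= protein_radius)
    stopf("site_radius must be < protein_radius")
  channels <- lapply(channels, function(ch) {
    ax <- as.numeric(ch$axis)
    if (length(ax) != 3 || sqrt(sum(ax^2)) == 0)
      stopf("each channel axis must be a nonzero 3-vector")
    r <- ch$radius
    check_positive(r, "channel radius")
    if (r >= protein_radius) stopf("channel radius must be < protein_radius")
    list(axis = ax / sqrt(sum(ax^2)), radius = r)
  })
  structure(
    list(box_edge = box_edge, protein_center = protein_center,
         protein_radius = protein_radius, channels = channels,
         site_radius = site_radius, diffusion_coeff = diffusion_coeff,
         timestep = timestep, contact_cutoff = contact_cutoff),
    class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf(
    "toy_system: box %.2f nm, protein R %.2f nm, site R %.2f nm, %d channel(s), D %.2f nm^2/ns, dt %.4g ns\n",
    x$box_edge, x$protein_radius, x$site_radius, length(x$channels),
    x$diffusion_coeff, x$timestep))
  invisible(x)
}

# channel membership for positions relative to the protein centre.
# d: n x 3 matrix of minimum-image displacements; returns list(ch = integer
# channel index or NA, nearest = index of channel with smallest perpendicular
# distance to the axis ray). A point is inside channel c when its distance to
# the axis ray is below the channel radius and its along-axis coordinate lies
# in [site_radius, protein_radius + channel_radius] (finite mouth outside the
# surface). Ties go to the lowest channel index.
.channel_membership <- function(d, r, system) {
  n <- nrow(d)
  ncx <- length(system$channels)
  ch <- rep(NA_integer_, n)
  if (ncx == 0L) return(list(ch = ch, nearest = ch))
  perp_all <- matrix(Inf, n, ncx)
  for (c in seq_len(ncx)) {
    cc <- system$channels[[c]]
    t_ax <- drop(d %*% cc$axis)
    perp2 <- pmax(r^2 - t_ax^2, 0)
    perp <- ifelse(t_ax < 0, r, sqrt(perp2))
    perp_all[, c] <- perp
    inside <- perp < cc$radius &
      t_ax >= system$site_radius &
      t_ax <= system$protein_radius + cc$radius
    ch[inside & is.na(ch)] <- c
  }
  nearest <- max.col(-perp_all, ties.method = "first")
  list(ch = ch, nearest = nearest)
}

#' Simulate gas-ligand diffusion in a toy system
#'
#' Overdamped Brownian dynamics of `n_ligands` independent point ligands in
#' a periodic box: Gaussian displacements with per-axis variance `2 D dt`,
#' periodic wrapping, and rejection (the ligand stays in place) of any step
#' that would enter the protein sphere outside a channel or the site.
#' Reaching the site sphere records a binding event; a subsequent exit to
#' bulk records an unbinding event. The channel attributed to an event is
#' the channel containing the ligand at the frame it crossed the
#' protein-radius shell (lowest index on ties).
#'
#' @param system a [toy_system()].
#' @param n_ligands number of ligand copies (>= 1).
#' @param n_frames number of saved frames (>= 2), including the initial one.
#' @param seed integer RNG seed; the run is fully reproducible from it.
#'
#' @return an object of class `toy_trajectory`: list with `positions`
#'   (array frame x ligand x 3, nm, wrapped into the box), `events`
#'   (data.frame: ligand, type "binding"/"unbinding", frame, channel),
#'   `system`, `times` (ns) and `seed`.
#' @export
#' @examples
#' traj <- simulate_ligand_diffusion(toy_system(), n_ligands = 4,
#'                                   n_frames = 200, seed = 1)
#' dim(traj$positions)
simulate_ligand_diffusion <- function(system, n_ligands, n_frames, seed) {
  stopifnot(inherits(system, "toy_system"))
  if (n_ligands < 1) stopf("n_ligands must be >= 1")
  if (n_frames < 2) stopf("n_frames must be >= 2")
  R <- system$protein_radius
  site <- system$site_radius
  bulk <- R + system$contact_cutoff
  box <- rep(system$box_edge, 3)
  ctr <- system$protein_center
  sd_step <- sqrt(2 * system$diffusion_coeff * system$timestep)

  with_seed(seed, {
    # initial positions: uniform in the box, outside the bulk shell
    pos <- matrix(NA_real_, n_ligands, 3)
    need <- rep(TRUE, n_ligands)
    while (any(need)) {
      m <- sum(need)
      cand <- matrix(stats::runif(3 * m, 0, system$box_edge), m, 3)
      r <- min_image_dist(ctr, cand, box)
      ok <- r > bulk
      pos[which(need)[ok], ] <- cand[ok, , drop = FALSE]
      need[which(need)[ok]] <- FALSE
    }
    steps <- array(stats::rnorm((n_frames - 1) * n_ligands * 3, 0, sd_step),
                   dim = c(n_frames - 1, n_ligands, 3))

    positions <- array(NA_real_, dim = c(n_frames, n_ligands, 3))
    positions[1, , ] <- pos
    d0 <- min_image(sweep(pos, 2, ctr), box)
    r_cur <- sqrt(rowSums(d0^2))
    bound <- rep(FALSE, n_ligands)
    entry_ch <- rep(NA_integer_, n_ligands)
    exit_ch <- rep(NA_integer_, n_ligands)
    cur_m <- rep(NA_integer_, n_ligands)   # channel of the current position
    last_ch <- rep(NA_integer_, n_ligands) # most recent channel occupied
    ev_lig <- integer(0); ev_type <- character(0)
    ev_frame <- integer(0); ev_ch <- integer(0)

    for (f in 2:n_frames) {
      prop <- wrap_box(pos + steps[f - 1, , , drop = TRUE], box)
      if (n_ligands == 1) prop <- matrix(prop, 1, 3)
      d <- min_image(sweep(prop, 2, ctr), box)
      r_new <- sqrt(rowSums(d^2))
      memb <- .channel_membership(d, r_new, system)
      # a move is legal if it ends in bulk/surface region, in a channel, or
      # in the site -- but direct jumps between the site and the outside of
      # the shell (skipping the channels entirely) are rejected in both
      # directions: they would tunnel through the protein wall
      accept <- (r_new >= R & r_cur > site) |
                (r_new <= site & r_cur <= R) |
                !is.na(memb$ch)
      pos[accept, ] <- prop[accept, , drop = FALSE]
      r_acc <- ifelse(accept, r_new, r_cur)
      cur_m <- ifelse(accept, memb$ch, cur_m)
      last_ch <- ifelse(is.na(cur_m), last_ch, cur_m)

      # shell crossings (accepted moves only). A crossing point can fall in
      # the gap between channel cones (moves outward past the shell are
      # always accepted); the transited channel is then the one most
      # recently occupied.
      entered <- accept & r_cur > R & r_new <= R
      exited <- accept & r_cur <= R & r_new > R
      if (any(entered)) {
        i <- which(entered)
        entry_ch[i] <- ifelse(is.na(memb$ch[i]), last_ch[i], memb$ch[i])
      }
      if (any(exited)) {
        i <- which(exited)
        exit_ch[i] <- ifelse(is.na(memb$ch[i]), last_ch[i], memb$ch[i])
      }

      newly_bound <- !bound & r_acc <= site
      if (any(newly_bound)) {
        i <- which(newly_bound)
        ev_lig <- c(ev_lig, i)
        ev_type <- c(ev_type, rep("binding", length(i)))
        ev_frame <- c(ev_frame, rep(f, length(i)))
        ev_ch <- c(ev_ch, entry_ch[i])
        bound[i] <- TRUE
      }
      newly_unbound <- bound & r_acc > bulk
      if (any(newly_unbound)) {
        i <- which(newly_unbound)
        ev_lig <- c(ev_lig, i)
        ev_type <- c(ev_type, rep("unbinding", length(i)))
        ev_frame <- c(ev_frame, rep(f, length(i)))
        ev_ch <- c(ev_ch, exit_ch[i])
        bound[i] <- FALSE
      }
      r_cur <- r_acc
      positions[f, , ] <- pos
    }

    events <- data.frame(ligand = ev_lig, type = ev_type,
                         frame = ev_frame, channel = ev_ch)
    events <- events[order(events$ligand, events$frame), , drop = FALSE]
    rownames(events) <- NULL
    structure(
      list(positions = positions, events = events, system = system,
           times = (seq_len(n_frames) - 1) * system$timestep, seed = seed),
      class = "toy_trajectory")
  })
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf(
    "toy_trajectory: %d frames x %d ligands (%.1f ns), %d ground-truth events, seed %s\n",
    dim(x$positions)[1], dim(x$positions)[2], max(x$times),
    nrow(x$events), format(x$seed)))
  invisible(x)
}

#' Generate a two-state Gaussian-emission time series
#'
#' Simulates a hidden two-state Markov chain (states 0 and 1) started from
#' its stationary distribution, with Gaussian emissions per state. This is a
#' synthetic stand-in for a bimodal gating coordinate such as a bottleneck
#' residue-pair distance with open and closed states.
#'
#' @param transition_probs numeric `c(p01, p10)`: per-frame switching
#'   probabilities 0->1 and 1->0, both in (0, 1). The stationary occupancy of
#'   state 0 is `p10 / (p01 + p10)`.
#' @param emissions list of two `c(mean, sd)` pairs (Angstrom), for states 0
#'   and 1.
#' @param n_frames series length.
#' @param seed integer RNG seed.
#'
#' @return object of class `two_state_series`: list with `values` (Angstrom),
#'   `hidden_states` (0/1), `transition_probs`, `emissions`, `seed`.
#' @export
#' @examples
#' ts <- generate_two_state_series(c(0.01, 0.03),
#'                                 list(c(4.5, 0.3), c(7.5, 0.5)),
#'                                 n_frames = 1000, seed = 1)
#' mean(ts$hidden_states == 0)
generate_two_state_series <- function(transition_probs, emissions, n_frames,
                                      seed) {
  p01 <- transition_probs[1]; p10 <- transition_probs[2]
  if (!(p01 > 0 && p01 < 1 && p10 > 0 && p10 < 1))
    stopf("transition probabilities must lie strictly in (0, 1)")
  if (length(emissions) != 2)
    stopf("emissions must be a list of two c(mean, sd) pairs")
  mu <- vapply(emissions, `[`, numeric(1), 1)
  sd <- vapply(emissions, `[`, numeric(1), 2)
  if (any(sd <= 0)) stopf("emission standard deviations must be > 0")
  if (abs(mu[1] - mu[2]) < (sd[1] + sd[2]))
    warning("emission modes closer than the sum of their sds; ",
            "states may not be separable", call. = FALSE)
  if (n_frames < 1) stopf("n_frames must be >= 1")

  with_seed(seed, {
    pi0 <- p10 / (p01 + p10)
    s <- integer(n_frames)
    u <- stats::runif(n_frames)
    s[1] <- as.integer(u[1] >= pi0)  # start from stationary distribution
    if (n_frames > 1) {
      for (t in 2:n_frames) {
        s[t] <- if (s[t - 1] == 0L) as.integer(u[t] < p01)
                else 1L - as.integer(u[t] < p10)
      }
    }
    vals <- stats::rnorm(n_frames, mean = mu[s + 1], sd = sd[s + 1])
    structure(
      list(values = vals, hidden_states = s,
           transition_probs = c(p01 = p01, p10 = p10),
           emissions = list(state0 = c(mean = mu[1], sd = sd[1]),
                            state1 = c(mean = mu[2], sd = sd[2])),
           seed = seed),
      class = "two_state_series")
  })
}

#' Tunnel objects matching a toy system's channels
#'
#' Builds one [Tunnel][load_tunnels] per channel of a toy system: sphere
#' centres placed along the channel axis from the site-sphere surface to one
#' channel radius beyond the protein surface, spaced half a channel radius
#' apart, each with the channel radius. Coordinates are in Angstrom, matching
#' the analysis interface.
#'
#' @param system a [toy_system()].
#' @return list of `tunnel` objects (ids "T1", "T2", ...).
#' @export
toy_tunnels <- function(system) {
  stopifnot(inherits(system, "toy_system"))
  if (length(system$channels) == 0) stopf("system has no channels")
  lapply(seq_along(system$channels), function(c) {
    cc <- system$channels[[c]]
    t_end <- system$protein_radius + cc$radius
    t_seq <- seq(system$site_radius, t_end, by = cc$radius / 2)
    if (t_seq[length(t_seq)] < t_end) t_seq <- c(t_seq, t_end)
    centers <- t(vapply(t_seq,
                        function(t) system$protein_center + t * cc$axis,
                        numeric(3)))
    new_tunnel(id = paste0("T", c),
               centers = nm_to_ang(centers),
               radii = rep(nm_to_ang(cc$radius), length(t_seq)))
  })
}
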