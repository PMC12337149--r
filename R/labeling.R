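#' Define the binding site for state labeling
#'
#' Describes the buried catalytic site: the atom group whose centre of mass
#' defines the site, and the two anchor atoms (e.g. the Ni and Fe of a
#' [NiFe] centre) whose midpoint defines the metal interface. A ligand is
#' bound when its centre of mass is within `bound_cutoff` of the site centre
#' of mass AND within `interface_cutoff` of the anchor midpoint.
#'
#' The interface criterion operationalises "near the metal interface" as a
#' midpoint distance; the 3 Angstrom default is configurable.
#'
#' @param site_atoms integer atom indices (rows of the trajectory atom
#'   table) forming the site group.
#' @param anchor_pair list of two integer index vectors, one per anchor
#'   atom (each usually length 1).
#' @param bound_cutoff bound-state distance cutoff (Angstrom), default 5.
#' @param interface_cutoff anchor-midpoint cutoff (Angstrom), default 3.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(site_atoms, anchor_pair,
                            bound_cutoff = 5, interface_cutoff = 3) {
  if (length(site_atoms) == 0) stopf("site_atoms selection is empty")
  if (length(anchor_pair) != 2 || any(lengths(anchor_pair) == 0))
    stopf("anchor_pair must be a list of two non-empty atom selections")
  check_positive(bound_cutoff, "bound_cutoff")
  check_positive(interface_cutoff, "interface_cutoff")
  structure(list(site_atoms = as.integer(site_atoms),
                 anchor_pair = lapply(anchor_pair, as.integer),
                 bound_cutoff = bound_cutoff,
                 interface_cutoff = interface_cutoff),
            class = "site_definition")
}

.new_state_series <- function(ligand, labels, frame_times, com,
                              surface_dist, contact_cutoff, replica = 1L) {
  stopifnot(length(labels) == length(frame_times),
            nrow(com) == length(labels))
  if (any(diff(frame_times) <= 0))
    stopf("frame_times must be strictly increasing")
  structure(list(ligand = ligand, replica = replica, labels = labels,
                 frame_times = frame_times, com = com,
                 surface_dist = surface_dist,
                 contact_cutoff = contact_cutoff),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  tab <- table(factor(x$labels, c("bound", "intermediate", "unbound")))
  cat(sprintf("state_series ligand %s: %d frames (B %d / I %d / U %d)\n",
              format(x$ligand), length(x$labels), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Label ligand frames as bound / intermediate / unbound
#'
#' Per ligand copy and frame: bound when the ligand centre of mass is within
#' `bound_cutoff` of the site centre of mass and within `interface_cutoff`
#' of the anchor midpoint; unbound when the minimum ligand-atom to
#' protein-atom distance exceeds `contact_cutoff` (no protein contact);
#' intermediate otherwise. All distances use the minimum-image convention.
#'
#' @param trajectory an [md_trajectory][read_md_trajectory] or
#'   [toy_trajectory][simulate_ligand_diffusion].
#' @param site a [site_definition()] (ignored for toy trajectories, whose
#'   site is the buried sphere).
#' @param contact_cutoff protein-contact cutoff (Angstrom), default 4.
#' @param ... method-specific arguments.
#' @return list of `state_series`, one per ligand copy.
#' @export
label_frames <- function(trajectory, site = NULL, contact_cutoff = 4, ...) {
  UseMethod("label_frames")
}

#' @rdname label_frames
#' @export
label_frames.toy_trajectory <- function(trajectory, site = NULL,
                                        contact_cutoff = 4, ...) {
  sys <- trajectory$system
  nf <- dim(trajectory$positions)[1]
  nl <- dim(trajectory$positions)[2]
  box <- rep(sys$box_edge, 3)
  bound_cut_nm <- if (is.null(site)) sys$site_radius
                  else ang_to_nm(site$bound_cutoff)
  contact_nm <- ang_to_nm(contact_cutoff)
  lapply(seq_len(nl), function(l) {
    p <- trajectory$positions[, l, , drop = TRUE]
    if (nf == 1) p <- matrix(p, 1, 3)
    r <- min_image_dist(sys$protein_center, p, box)
    labels <- ifelse(r <= bound_cut_nm, "bound",
                     ifelse(r - sys$protein_radius > contact_nm,
                            "unbound", "intermediate"))
    .new_state_series(ligand = l, labels = labels,
                      frame_times = trajectory$times,
                      com = nm_to_ang(p),
                      surface_dist = nm_to_ang(r - sys$protein_radius),
                      contact_cutoff = contact_cutoff)
  })
}

#' @rdname label_frames
#' @param ligands list of integer atom-index vectors, one per ligand copy.
#' @param protein integer indices of protein atoms used for the contact
#'   criterion; defaults to every heavy atom not in a ligand.
#' @export
label_frames.md_trajectory <- function(trajectory, site,
                                       contact_cutoff = 4,
                                       ligands, protein = NULL, ...) {
  if (!inherits(site, "site_definition"))
    stopf("'site' must be a site_definition")
  if (missing(ligands) || length(ligands) == 0)
    stopf("'ligands' selection is empty")
  check_positive(contact_cutoff, "contact_cutoff")
  nf <- dim(trajectory$xyz)[1]
  if (is.null(protein)) {
    lig_idx <- unlist(ligands)
    heavy <- !grepl("^H", trimws(trajectory$atoms$elety))
    protein <- setdiff(which(heavy), lig_idx)
  }
  if (length(protein) == 0) stopf("protein selection is empty")
  masses <- .atom_masses(trajectory$atoms)

  lapply(seq_along(ligands), function(l) {
    idx <- as.integer(ligands[[l]])
    labels <- character(nf)
    com <- matrix(NA_real_, nf, 3)
    sdist <- numeric(nf)
    for (f in seq_len(nf)) {
      box <- .frame_box(trajectory, f)
      xyz <- trajectory$xyz[f, , ]
      lcom <- .weighted_com(xyz[idx, , drop = FALSE], masses[idx], box)
      scom <- .weighted_com(xyz[site$site_atoms, , drop = FALSE],
                            masses[site$site_atoms], box)
      a1 <- .weighted_com(xyz[site$anchor_pair[[1]], , drop = FALSE],
                          masses[site$anchor_pair[[1]]], box)
      a2 <- .weighted_com(xyz[site$anchor_pair[[2]], , drop = FALSE],
                          masses[site$anchor_pair[[2]]], box)
      mid <- a1 + min_image(a2 - a1, box) / 2
      d_site <- sqrt(sum(min_image(lcom - scom, box)^2))
      d_int <- sqrt(sum(min_image(lcom - mid, box)^2))
      dmin <- min(vapply(idx, function(a)
        min(min_image_dist(xyz[a, ], xyz[protein, , drop = FALSE], box)),
        numeric(1)))
      labels[f] <- if (d_site <= site$bound_cutoff &&
                       d_int <= site$interface_cutoff) "bound"
                   else if (dmin > contact_cutoff) "unbound"
                   else "intermediate"
      com[f, ] <- lcom
      sdist[f] <- dmin
    }
    .new_state_series(ligand = l, labels = labels,
                      frame_times = trajectory$times,
                      com = com, surface_dist = sdist,
                      contact_cutoff = contact_cutoff)
  })
}

.weighted_com <- function(xyz, w, box) {
  if (nrow(xyz) == 1) return(drop(xyz))
  # unwrap relative to the first atom before averaging (minimum image)
  ref <- xyz[1, ]
  rel <- min_image(sweep(xyz, 2, ref), box)
  ref + colSums(rel * w) / sum(w)
}

.atom_masses <- function(atoms) {
  m <- tryCatch(bio3d::atom2mass(atoms$elety),
                error = function(e) NULL, warning = function(w) NULL)
  if (is.null(m) || any(!is.finite(m))) m <- rep(1, nrow(atoms))
  m
}

#' Extract binding and unbinding events from a labelled series
#'
#' A binding event is emitted at the first frame of a run of at least
#' `min_dwell` consecutive bound frames following the most recent run of at
#' least `min_dwell` unbound frames (the ligand is assumed unbound at the
#' start of a replica); the symmetric rule yields unbinding events. The
#' first-passage time (FPT) of the first binding of a replica is measured
#' from frame one; subsequent FPTs from the completing frame of the
#' preceding unbinding (set `fpt_from = "replica_start"` to always measure
#' from frame one). Residence time runs from binding completion to
#' unbinding completion. Each event carries a crossing trace: ligand
#' centre-of-mass positions in a window around the surface crossing (last
#' inward crossing for binding, first outward crossing for unbinding),
#' where the surface is the protein-contact distance crossing
#' `contact_cutoff`.
#'
#' @param series a `state_series` from [label_frames()], or a list of them.
#' @param min_dwell minimum run length (frames) for a state to count,
#'   default 1; larger values suppress recrossing noise.
#' @param trace_window half-width (frames) of the crossing-trace window,
#'   default 25 (wide enough to cover the full channel transit on either
#'   side of the surface crossing).
#' @param fpt_from `"previous_unbinding"` (default) or `"replica_start"`.
#' @return object of class `event_table`: a data.frame with one row per
#'   event (type, ligand, replica, start_frame, end_frame, passage_time in
#'   ns) and a `traces` attribute holding, per event, a list with `points`
#'   (matrix, Angstrom), `outside` (logical) and `frames`.
#' @export
extract_events <- function(series, min_dwell = 1, trace_window = 25,
                           fpt_from = c("previous_unbinding",
                                        "replica_start")) {
  fpt_from <- match.arg(fpt_from)
  if (min_dwell < 1) stopf("min_dwell must be >= 1")
  if (is.list(series) && !inherits(series, "state_series")) {
    parts <- lapply(series, extract_events, min_dwell = min_dwell,
                    trace_window = trace_window, fpt_from = fpt_from)
    return(.bind_event_tables(parts))
  }
  x <- series
  n <- length(x$labels)
  outside <- x$surface_dist > x$contact_cutoff
  rl <- rle(x$labels)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L

  cur <- "unbound"
  ref_frame <- 1L      # FPT reference
  bind_frame <- NA_integer_
  rows <- list(); traces <- list()

  add_event <- function(type, start_f, end_f) {
    pt <- x$frame_times[end_f] - x$frame_times[start_f]
    cross <- if (type == "binding") .last_inward_crossing(outside, end_f)
             else .first_outward_crossing(outside, bind_frame)
    tr <- NULL
    if (!is.na(cross)) {
      # the window is extended so it always covers the channel transit:
      # up to the completion frame for binding, and far enough back to
      # include the climb to the surface for unbinding
      w <- if (type == "binding")
        max(1L, cross - trace_window):min(n, max(end_f, cross + trace_window))
      else
        max(1L, cross - 10L * trace_window):min(n, cross + trace_window)
      tr <- list(points = x$com[w, , drop = FALSE], outside = outside[w],
                 surface_dist = x$surface_dist[w], labels = x$labels[w],
                 frames = w)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, ligand = x$ligand, replica = x$replica,
      start_frame = start_f, end_frame = end_f,
      start_time = x$frame_times[start_f], end_time = x$frame_times[end_f],
      passage_time = pt)
    traces[length(rows)] <<- list(tr)   # keeps NULL traces in place
  }

  for (k in seq_along(rl$values)) {
    s <- rl$values[k]; L <- rl$lengths[k]; i <- starts[k]
    if (s == "bound" && L >= min_dwell && cur == "unbound") {
      add_event("binding", ref_frame, i)
      cur <- "bound"; bind_frame <- i
    } else if (s == "unbound" && L >= min_dwell && cur == "bound") {
      add_event("unbinding", bind_frame, i)
      cur <- "unbound"
      if (fpt_from == "previous_unbinding") ref_frame <- i
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(type = character(0), ligand = integer(0),
                        replica = integer(0), start_frame = integer(0),
                        end_frame = integer(0), start_time = numeric(0),
                        end_time = numeric(0), passage_time = numeric(0))
  rownames(df) <- NULL
  attr(df, "traces") <- traces
  class(df) <- c("event_table", "data.frame")
  df
}

.last_inward_crossing <- function(outside, before) {
  if (before < 2) return(NA_integer_)
  k <- which(outside[1:(before - 1)] & !outside[2:before])
  if (length(k) == 0) NA_integer_ else max(k) + 1L
}

.first_outward_crossing <- function(outside, after) {
  n <- length(outside)
  if (is.na(after) || after >= n) return(NA_integer_)
  k <- which(!outside[after:(n - 1)] & outside[(after + 1):n])
  if (length(k) == 0) NA_integer_ else after + min(k)
}

.bind_event_tables <- function(parts) {
  dfs <- lapply(parts, function(p) { attr(p, "traces") <- NULL
                                     class(p) <- "data.frame"; p })
  df <- do.call(rbind, dfs)
  rownames(df) <- NULL
  attr(df, "traces") <- do.call(c, lapply(parts, attr, "traces"))
  class(df) <- c("event_table", "data.frame")
  df
}

#' Surface crossing point of an event
#'
#' Returns the trace point where the event crossed the protein surface: the
#' last point outside the surface before entry for binding events, or the
#' first point outside the surface after exit for unbinding events. The
#' surface is defined by the protein-contact distance crossing the contact
#' cutoff used at labelling time.
#'
#' @param events an `event_table` from [extract_events()].
#' @param i event row index.
#' @return list with `point` (3-vector, Angstrom), `frame`, and `crossing`
#'   (FALSE when the trace never crosses the surface; such events are
#'   excluded from pathway assignment with a warning).
#' @export
surface_crossing_point <- function(events, i) {
  tr <- attr(events, "traces")[[i]]
  no <- list(point = NULL, frame = NA_integer_, crossing = FALSE)
  if (is.null(tr)) return(no)
  out <- tr$outside
  n <- length(out)
  k <- if (events$type[i] == "binding") {
    # last entry before the binding completed
    j <- which(out[seq_len(n - 1)] & !out[-1] &
                 tr$frames[-1] <= events$end_frame[i])
    if (length(j)) max(j) else NA_integer_
  } else {
    # first exit after the binding that this unbinding terminates
    j <- which(!out[seq_len(n - 1)] & out[-1] &
                 tr$frames[seq_len(n - 1)] >= events$start_frame[i])
    if (length(j)) min(j) + 1L else NA_integer_
  }
  if (is.na(k)) return(no)
  list(point = tr$points[k, ], frame = tr$frames[k], crossing = TRUE)
}

#' Write an event table to CSV
#'
#' One row per event; crossing traces are not serialised.
#' @param events an `event_table`.
#' @param file output path.
#' @export
write_events_csv <- function(events, file) {
  df <- events; attr(df, "traces") <- NULL; class(df) <- "data.frame"
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
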