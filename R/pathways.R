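#' Construct a tunnel object
#'
#' A tunnel is an ordered list of spheres (centre + radius, Angstrom) from
#' the buried site to the protein surface, as produced by sphere-based
#' tunnel-detection tools.
#'
#' @param id tunnel identifier, e.g. `"T1"`.
#' @param centers numeric matrix (n x 3) of sphere centres (Angstrom).
#' @param radii sphere radii (Angstrom), length n.
#' @return object of class `tunnel`.
#' @export
new_tunnel <- function(id, centers, radii) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2) stopf("tunnel '%s' needs >= 2 spheres", id)
  if (length(radii) != nrow(centers))
    stopf("tunnel '%s': radii/centers length mismatch", id)
  if (any(radii <= 0)) stopf("tunnel '%s': radii must be > 0", id)
  structure(list(id = id, centers = unname(centers),
                 radii = as.numeric(radii)), class = "tunnel")
}

#' @export
print.tunnel <- function(x, ...) {
  cat(sprintf("tunnel %s: %d spheres, radii %.2f-%.2f A\n", x$id,
              nrow(x$centers), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Read tunnels from a sphere-record PDB file
#'
#' Parses the sphere dialect written by tunnel-detection tools such as
#' CAVER: one ATOM/HETATM record per sphere, tunnel (cluster) id in the
#' residue-number field, sphere radius in the B-factor field. Within each
#' tunnel, spheres are ordered by distance from `site_anchor` (site-first)
#' when an anchor is given, otherwise kept in file order.
#'
#' @param path PDB-format sphere file.
#' @param site_anchor optional 3-vector (Angstrom): the buried-site
#'   reference point used to orient each tunnel site-first.
#' @return list of [tunnel][new_tunnel] objects, ids `"T<cluster>"` in
#'   ascending cluster order.
#' @export
load_tunnels <- function(path, site_anchor = NULL) {
  if (!file.exists(path)) stopf("tunnel file not found: %s", path)
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54),
              substr(ln, 61, 66), substr(ln, 23, 26))
    if (any(is.na(suppressWarnings(as.numeric(flds)))))
      stopf("malformed sphere record at line %d of %s", i, path)
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (nrow(at) == 0) stopf("no sphere records in %s", path)
  ids <- sort(unique(at$resno))
  tunnels <- lapply(ids, function(cid) {
    sel <- at$resno == cid
    centers <- as.matrix(at[sel, c("x", "y", "z")])
    radii <- at$b[sel]
    if (!is.null(site_anchor)) {
      d <- sqrt(colSums((t(centers) - site_anchor)^2))
      o <- order(d)
      centers <- centers[o, , drop = FALSE]
      radii <- radii[o]
    }
    new_tunnel(paste0("T", cid), centers, radii)
  })
  if (length(tunnels) == 0) stopf("zero tunnels in %s", path)
  tunnels
}

#' Write tunnels to a sphere-record PDB file
#'
#' Inverse of [load_tunnels()]: cluster id in the residue-number field,
#' radius in the B-factor field.
#'
#' @param tunnels list of [tunnel][new_tunnel] objects.
#' @param path output path.
#' @export
write_tunnels <- function(tunnels, path) {
  centers <- do.call(rbind, lapply(tunnels, `[[`, "centers"))
  radii <- unlist(lapply(tunnels, `[[`, "radii"))
  cid <- unlist(lapply(tunnels, function(t)
    rep(as.integer(sub("^T", "", t$id)), nrow(t$centers))))
  n <- nrow(centers)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(centers)),
                   type = rep("HETATM", n), eleno = seq_len(n),
                   elety = rep("SPH", n), resid = rep("TUN", n),
                   resno = cid, chain = rep("A", n), b = radii)
  invisible(path)
}

# per-point minimum surface-excess distance over all tunnels
.point_excess <- function(points, tunnels) {
  apply(points, 1, function(p) {
    min(vapply(tunnels, function(tu) {
      d <- sqrt(colSums((t(tu$centers) - p)^2))
      j <- which.min(d)
      max(0, d[j] - tu$radii[j])
    }, numeric(1)))
  })
}

# mean surface-excess distance of trace points to a tunnel's spheres
.tunnel_score <- function(points, tunnel) {
  ex <- apply(points, 1, function(p) {
    d <- sqrt(colSums((t(tunnel$centers) - p)^2))
    j <- which.min(d)
    max(0, d[j] - tunnel$radii[j])
  })
  mean(ex)
}

#' Assign a crossing trace to a tunnel
#'
#' Scores each tunnel by the mean, over trace points, of the distance to
#' the nearest sphere centre minus that sphere's radius (floored at zero),
#' and returns the id of the lowest-scoring tunnel if its score is at most
#' `max_assign_dist`, else `"unassigned"`. Ties break by tunnel list order.
#'
#' @param trace numeric matrix (n x 3) of trace points (Angstrom).
#' @param tunnels list of [tunnel][new_tunnel] objects.
#' @param max_assign_dist assignment threshold (Angstrom), default 3.
#' @return a tunnel id or `"unassigned"`.
#' @export
assign_event <- function(trace, tunnels, max_assign_dist = 3) {
  if (length(tunnels) == 0) stopf("empty tunnel list")
  if (is.null(trace) || nrow(trace) == 0) stopf("empty crossing trace")
  scores <- vapply(tunnels, .tunnel_score, numeric(1), points = trace)
  j <- which.min(scores)
  if (scores[j] <= max_assign_dist) tunnels[[j]]$id else "unassigned"
}

#' Assign every event of an event table to a tunnel
#'
#' Scoring uses the channel-discriminating part of each crossing trace:
#' the contiguous run of in-channel points (inside the protein surface
#' but not in the bound site) adjacent to the event,
#' trimmed to the points nearest the surface crossing (the descent from
#' the surface for binding, the climb toward it for unbinding), falling
#' back to the surface crossing point when the window holds no inside
#' points. Bulk frames far from any tunnel mouth and deep-site frames
#' near every tunnel's innermost spheres therefore never dilute the
#' match.
#' Events whose trace never crosses the protein surface are excluded with
#' a warning and reported as `NA`.
#'
#' @param events an [event_table][extract_events].
#' @param tunnels list of tunnels.
#' @param max_assign_dist threshold (Angstrom), default 3.
#' @param n_keep number of transit points nearest the surface crossing to
#'   score, default 1: the event is assigned by its entry/exit point.
#'   Larger values average over the adjacent transit and are more robust
#'   to noisy single frames, at the cost of blurring events that switch
#'   channels deep inside the protein.
#' @return character vector of tunnel ids / `"unassigned"` / `NA` per event.
#' @export
assign_events <- function(events, tunnels, max_assign_dist = 3,
                          n_keep = 1L) {
  n <- nrow(events)
  out <- rep(NA_character_, n)
  n_skip <- 0
  for (i in seq_len(n)) {
    cp <- surface_crossing_point(events, i)
    if (!isTRUE(cp$crossing)) { n_skip <- n_skip + 1; next }
    tr <- attr(events, "traces")[[i]]
    binding <- events$type[i] == "binding"
    clip <- if (binding) events$end_frame[i] else cp$frame
    # transit: inside the protein surface or inside a tunnel sphere (the
    # mouth region extends past the surface), never the bound site
    in_tunnel <- .point_excess(tr$points, tunnels) <= 1e-9
    transit <- (tr$surface_dist < 0 | in_tunnel) & tr$labels != "bound"
    use <- .decisive_points(transit, tr$surface_dist < 0, tr$frames,
                            clip, cp$frame, binding, n_keep = n_keep)
    if (!any(use)) use <- tr$frames == cp$frame
    out[i] <- assign_event(tr$points[use, , drop = FALSE], tunnels,
                           max_assign_dist)
  }
  if (n_skip > 0)
    warning(sprintf(
      "%d event(s) had no surface crossing and were excluded from pathway assignment",
      n_skip), call. = FALSE)
  out
}

# channel-discriminating points of a crossing trace: the transit points
# nearest the decisive protein-shell crossing. For binding that crossing
# is the start of the final inside-surface segment before the event
# completes (a trace may hold several entries when the ligand pops out
# into a mouth and re-enters); for unbinding it is the last
# inside-to-outside transition before the bulk crossing. Transit points
# are those in a channel or its mouth region and never in the bound
# site, so deep-site frames and bulk frames never enter the score. On
# ties, binding prefers points at/after the entry and unbinding points
# at/before the exit, mirroring how the generator of the toy system
# attributes a channel (membership at the crossing frame, falling back
# to the channel most recently occupied).
.decisive_points <- function(transit, inside, frames, clip, cp_frame,
                             binding, n_keep = 1L) {
  n <- length(inside)
  j <- if (binding) {
    ent <- which(inside & !c(FALSE, inside[-n]))
    ent <- ent[frames[ent] <= clip]
    if (length(ent)) ent[length(ent)] else NA_integer_
  } else {
    ex <- which(!inside & c(FALSE, inside[-n]))
    ex <- ex[frames[ex] <= clip]
    if (length(ex)) ex[length(ex)] else NA_integer_
  }
  cand <- which(transit)
  out <- rep(FALSE, n)
  if (length(cand) == 0) return(out)
  if (is.na(j)) j <- which(frames == cp_frame)[1]
  tie <- if (binding) cand < j else cand > j
  keep <- cand[order(abs(cand - j), tie)][seq_len(min(n_keep,
                                                      length(cand)))]
  out[keep] <- TRUE
  out
}

#' Pathway probability distribution with bootstrap errors
#'
#' Counts and probabilities per tunnel id (plus `"unassigned"`), with
#' standard errors from bootstrap resampling of the assignment list.
#'
#' @param assignments character vector of tunnel ids / `"unassigned"`
#'   (`NA`s are dropped).
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed RNG seed.
#' @param categories optional category order (ids absent from
#'   `assignments` get zero counts).
#' @return object of class `pathway_distribution`: data.frame with columns
#'   pathway, count, probability, se, and attribute `n_events`.
#' @export
pathway_distribution <- function(assignments, n_boot = 1000, seed = NULL,
                                 categories = NULL) {
  assignments <- assignments[!is.na(assignments)]
  if (length(assignments) == 0) stopf("no assigned events")
  if (is.null(categories))
    categories <- c(sort(setdiff(unique(assignments), "unassigned")),
                    if ("unassigned" %in% assignments) "unassigned")
  f <- factor(assignments, levels = categories)
  if (any(is.na(f))) stopf("assignments outside the provided categories")
  counts <- as.integer(table(f))
  n <- length(assignments)
  probs <- counts / n
  ses <- with_seed(seed, {
    reps <- matrix(0, n_boot, length(categories))
    for (b in seq_len(n_boot)) {
      rs <- sample(assignments, n, replace = TRUE)
      reps[b, ] <- as.integer(table(factor(rs, levels = categories))) / n
    }
    apply(reps, 2, stats::sd)
  })
  out <- data.frame(pathway = categories, count = counts,
                    probability = probs, se = ses)
  attr(out, "n_events") <- n
  class(out) <- c("pathway_distribution", "data.frame")
  out
}

#' Two-sample chi-square comparison of pathway counts
#'
#' Standard chi-square test on the 2 x k contingency table of two count
#' vectors over the same categories (e.g. binding vs unbinding pathway
#' usage, testing detailed-balance symmetry). Categories whose expected
#' count falls below `min_expected` in either row are pooled into
#' `"other"`; if any expected count is still below the threshold, the
#' p-value is computed by Monte-Carlo resampling of tables with fixed
#' margins instead of the asymptotic chi-square distribution.
#'
#' @param counts_a,counts_b named integer vectors over identical category
#'   sets.
#' @param min_expected pooling threshold, default 5.
#' @param mc_replicates Monte-Carlo table draws, default 1e5.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param merge_map optional named character vector mapping category ->
#'   group, applied to both vectors before testing (e.g.
#'   `c(T1 = "T1+T2", T2 = "T1+T2")`).
#' @return object of class `symmetry_test`: list with `statistic`,
#'   `degrees_of_freedom`, `p_value`, `method` ("asymptotic" or
#'   "monte_carlo"), `pooled_categories`, `table`.
#' @export
#' @examples
#' chi_square_compare(c(a = 20, b = 10), c(a = 10, b = 20))
chi_square_compare <- function(counts_a, counts_b, min_expected = 5,
                               mc_replicates = 1e5, seed = NULL,
                               merge_map = NULL) {
  if (is.null(names(counts_a)) || is.null(names(counts_b)) ||
      !setequal(names(counts_a), names(counts_b)))
    stopf("counts_a and counts_b must be named over identical categories")
  counts_b <- counts_b[names(counts_a)]
  if (!is.null(merge_map)) {
    grp <- ifelse(names(counts_a) %in% names(merge_map),
                  merge_map[names(counts_a)], names(counts_a))
    counts_a <- tapply(counts_a, grp, sum)
    counts_b <- tapply(counts_b, grp, sum)
  }
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stopf("both samples must have positive totals")
  # drop categories empty in both samples
  keep <- (counts_a + counts_b) > 0
  counts_a <- counts_a[keep]; counts_b <- counts_b[keep]
  if (length(counts_a) == 1) {
    # both samples concentrated in one category: no heterogeneity to test
    return(structure(list(statistic = 0, degrees_of_freedom = 0L,
                          p_value = 1, method = "asymptotic",
                          pooled_categories = names(counts_a),
                          table = rbind(a = counts_a, b = counts_b)),
                     class = "symmetry_test"))
  }

  expected <- function(tab) {
    outer(rowSums(tab), colSums(tab)) / sum(tab)
  }
  tab <- rbind(a = counts_a, b = counts_b)
  e <- expected(tab)
  low <- apply(e, 2, min) < min_expected
  if (sum(low) > 1 && sum(!low) >= 1) {
    # pool only while at least two categories remain; an all-low table is
    # left intact and handled by the Monte-Carlo branch
    pooled <- c(colnames(tab)[!low], "other")
    tab <- cbind(tab[, !low, drop = FALSE],
                 other = rowSums(tab[, low, drop = FALSE]))
  } else {
    pooled <- colnames(tab)
  }
  if (ncol(tab) < 2) stopf("fewer than 2 categories after pooling")
  e <- expected(tab)
  stat <- sum((tab - e)^2 / e)
  dof <- ncol(tab) - 1L
  if (any(e < min_expected)) {
    method <- "monte_carlo"
    p <- with_seed(seed, {
      sims <- stats::r2dtable(mc_replicates, rowSums(tab), colSums(tab))
      stats_mc <- vapply(sims, function(tb) {
        eb <- expected(tb)
        sum((tb - eb)^2 / eb)
      }, numeric(1))
      (1 + sum(stats_mc >= stat - 1e-12)) / (mc_replicates + 1)
    })
  } else {
    method <- "asymptotic"
    p <- stats::pchisq(stat, dof, lower.tail = FALSE)
  }
  structure(list(statistic = stat, degrees_of_freedom = dof, p_value = p,
                 method = method, pooled_categories = pooled, table = tab),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g (%s; %d categories)\n",
              x$statistic, x$degrees_of_freedom, x$p_value, x$method,
              length(x$pooled_categories)))
  invisible(x)
}
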