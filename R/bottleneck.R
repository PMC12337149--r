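#' Per-frame minimum distance between two residues
#'
#' For each frame, the minimum over all pairs (one atom from each residue)
#' of the minimum-image atom-atom distance. Intended for bottleneck gating
#' pairs such as V74-L122; hydrogens are excluded by default because their
#' placement is force-field dependent.
#'
#' @param trajectory an [md_trajectory][read_md_trajectory].
#' @param residue_pair list of two integer atom-index vectors.
#' @param heavy_only drop atoms whose name starts with H, default TRUE.
#' @return object of class `bottleneck_series`: list with `distances`
#'   (Angstrom, per frame) and `frame_times` (ns).
#' @export
min_residue_distance <- function(trajectory, residue_pair,
                                 heavy_only = TRUE) {
  if (length(residue_pair) != 2 || any(lengths(residue_pair) == 0))
    stopf("residue_pair must be a list of two non-empty atom selections")
  a <- as.integer(residue_pair[[1]]); b <- as.integer(residue_pair[[2]])
  if (heavy_only) {
    hv <- !grepl("^H", trimws(trajectory$atoms$elety))
    a2 <- a[hv[a]]; b2 <- b[hv[b]]
    if (length(a2) && length(b2)) { a <- a2; b <- b2 }
  }
  nf <- dim(trajectory$xyz)[1]
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    box <- .frame_box(trajectory, f)
    xyz <- trajectory$xyz[f, , ]
    d[f] <- min(vapply(a, function(i)
      min(min_image_dist(xyz[i, ], xyz[b, , drop = FALSE], box)),
      numeric(1)))
  }
  structure(list(distances = d, frame_times = trajectory$times),
            class = "bottleneck_series")
}

#' Probability density of a distance series
#'
#' Normalised histogram (integral one) plus a Gaussian kernel density
#' estimate used for mode finding.
#'
#' @param series a `bottleneck_series`, `two_state_series`, or numeric
#'   vector of distances (Angstrom).
#' @param bin_width histogram bin width (Angstrom), default 0.2.
#' @param bandwidth kernel bandwidth; default lets [stats::density()]
#'   choose.
#' @return object of class `distance_density`: list with `breaks`, `mids`,
#'   `density` (histogram), `kde` (x, y), `values`.
#' @export
distance_density <- function(series, bin_width = 0.2, bandwidth = NULL) {
  x <- .series_values(series)
  if (length(x) < 2) stopf("need at least 2 frames")
  check_positive(bin_width, "bin_width")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  kde <- if (is.null(bandwidth)) stats::density(x)
         else stats::density(x, bw = bandwidth)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 kde = list(x = kde$x, y = kde$y), values = x,
                 bin_width = bin_width),
            class = "distance_density")
}

.series_values <- function(series) {
  if (inherits(series, "bottleneck_series")) series$distances
  else if (inherits(series, "two_state_series")) series$values
  else as.numeric(series)
}

# local maxima of y passing a prominence threshold (fraction of max y);
# prominence of a peak = height minus the highest valley separating it from
# higher terrain
.find_modes <- function(x, y, prominence = 0.05) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (length(idx) == 0) return(integer(0))
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    higher <- idx[y[idx] > y[i]]
    if (length(higher) == 0) { keep[k] <- TRUE; next }  # global max
    valleys <- vapply(higher, function(j)
      min(y[min(i, j):max(i, j)]), numeric(1))
    prom <- y[i] - max(valleys)
    keep[k] <- prom >= prominence * max(y)
  }
  idx[keep][order(y[idx[keep]], decreasing = TRUE)]
}

#' Two-state (open/closed) classification of a distance density
#'
#' If the smoothed density has two modes separated by a local minimum, the
#' minimum's location becomes the open/closed threshold; the open state is
#' the larger-distance mode and `open_fraction` is the fraction of frames
#' above the threshold. With a single mode the series is classified
#' unimodal and only that mode is reported.
#'
#' @param density a [distance_density()].
#' @param series optional series for the frame fractions; defaults to the
#'   values stored in `density`.
#' @param prominence minimum mode prominence as a fraction of the global
#'   density maximum, default 0.05.
#' @return object of class `two_state_summary`: list with `bimodal`,
#'   `mode_open`, `mode_closed`, `threshold`, `open_fraction` (Angstrom
#'   where applicable).
#' @export
classify_states <- function(density, series = NULL, prominence = 0.05) {
  stopifnot(inherits(density, "distance_density"))
  x <- if (is.null(series)) density$values else .series_values(series)
  kx <- density$kde$x; ky <- density$kde$y
  modes <- .find_modes(kx, ky, prominence)
  if (length(modes) < 2) {
    return(structure(list(bimodal = FALSE,
                          mode_open = NA_real_, mode_closed = NA_real_,
                          mode = if (length(modes)) kx[modes[1]] else NA_real_,
                          threshold = NA_real_, open_fraction = NA_real_),
                     class = "two_state_summary"))
  }
  m <- sort(kx[modes[1:2]])
  lo_i <- which.min(abs(kx - m[1])); hi_i <- which.min(abs(kx - m[2]))
  valley <- lo_i + which.min(ky[lo_i:hi_i]) - 1L
  thr <- kx[valley]
  structure(list(bimodal = TRUE, mode_open = m[2], mode_closed = m[1],
                 mode = kx[modes[1]], threshold = thr,
                 open_fraction = mean(x > thr)),
            class = "two_state_summary")
}

#' @export
print.two_state_summary <- function(x, ...) {
  if (x$bimodal)
    cat(sprintf(
      "bimodal: closed %.2f A / open %.2f A, threshold %.2f A, open fraction %.3f\n",
      x$mode_closed, x$mode_open, x$threshold, x$open_fraction))
  else
    cat(sprintf("unimodal: mode %.2f A\n", x$mode))
  invisible(x)
}

#' Write a distance density and two-state summary to CSV
#'
#' @param density a [distance_density()].
#' @param summary optional [classify_states()] result appended as comment
#'   metadata columns.
#' @param file output path.
#' @export
write_density_csv <- function(density, file, summary = NULL) {
  df <- data.frame(mid = density$mids, density = density$density)
  if (!is.null(summary) && isTRUE(summary$bimodal)) {
    df$mode_open <- summary$mode_open
    df$mode_closed <- summary$mode_closed
    df$threshold <- summary$threshold
    df$open_fraction <- summary$open_fraction
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
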