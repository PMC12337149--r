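#' @keywords internal
"_PACKAGE"

# Avogadro's number, 1/mol
.AVOGADRO <- 6.02214076e23

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Minimum-image displacement in an orthorhombic periodic box
#'
#' @param dx displacement matrix (n x 3) or vector of length 3.
#' @param box box edge lengths, length-3 vector (same units as `dx`).
#' @return wrapped displacements, same shape as `dx`.
#' @keywords internal
min_image <- function(dx, box) {
  if (is.null(box)) return(dx)
  if (is.matrix(dx)) {
    for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
    dx
  } else {
    dx - box * round(dx / box)
  }
}

#' Minimum-image distances between one point and a set of points
#' @keywords internal
min_image_dist <- function(p, pts, box) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  d <- sweep(pts, 2, p)
  d <- min_image(d, box)
  sqrt(rowSums(d^2))
}

#' Wrap coordinates into [0, box)
#' @keywords internal
wrap_box <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] %% box[k]
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stopf("'%s' must be a single positive number (got %s)", name,
          paste(format(x), collapse = ","))
  invisible(x)
}

#' Convert nanometres to Angstroms
#' @param x lengths in nm
#' @return lengths in Angstrom
#' @export
nm_to_ang <- function(x) x * 10

#' Convert Angstroms to nanometres
#' @param x lengths in Angstrom
#' @return lengths in nm
#' @export
ang_to_nm <- function(x) x / 10
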