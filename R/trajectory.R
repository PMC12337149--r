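#' Read a topology + trajectory into an md_trajectory
#'
#' Reads a PDB topology (optionally multi-model, in which case the models
#' are the frames) and, optionally, a DCD coordinate trajectory. All
#' coordinates are in Angstrom.
#'
#' @param topology path to a PDB file (read with [bio3d::read.pdb()]).
#' @param trajectory optional path to a DCD file
#'   ([bio3d::read.dcd()]); when absent, the PDB models are the frames.
#' @param dt time between frames (ns), default 1.
#' @param box orthorhombic box edge lengths (Angstrom, length 3). Defaults
#'   to the PDB CRYST1 record when present, otherwise `NULL` (no periodic
#'   wrapping).
#' @return object of class `md_trajectory`: list with `xyz` (array frame x
#'   atom x 3, Angstrom), `atoms` (the bio3d atom table), `box`, `times`
#'   (ns).
#' @export
read_md_trajectory <- function(topology, trajectory = NULL, dt = 1,
                               box = NULL) {
  pdb <- bio3d::read.pdb(topology, multi = is.null(trajectory))
  xyz <- if (is.null(trajectory)) pdb$xyz
         else bio3d::read.dcd(trajectory, verbose = FALSE)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  if (na != nrow(pdb$atom))
    stopf("trajectory has %d atoms but topology has %d", na, nrow(pdb$atom))
  arr <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, by = 3, length.out = na),
                                   drop = FALSE]
  if (is.null(box)) {
    cr <- grep("^CRYST1", readLines(topology, n = 50), value = TRUE)
    if (length(cr) >= 1)
      box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33)))
  }
  structure(list(xyz = arr, atoms = pdb$atom, box = box,
                 times = (seq_len(nf) - 1) * dt),
            class = "md_trajectory")
}

.frame_box <- function(trajectory, f) {
  b <- trajectory$box
  if (is.null(b)) return(NULL)
  if (is.matrix(b)) b[f, ] else b
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms%s\n",
              dim(x$xyz)[1], dim(x$xyz)[2],
              if (is.null(x$box)) "" else
                sprintf(", box %s A", paste(round(x$box, 1), collapse = "x"))))
  invisible(x)
}

#' Write a toy trajectory to a multi-model PDB with a JSON sidecar
#'
#' Each ligand becomes one HETATM pseudo-atom per model (frame), with a
#' CRYST1 record carrying the box. The recorded ground-truth events, frame
#' times and seed are serialised to `<file>.json`.
#'
#' @param traj a [toy_trajectory][simulate_ligand_diffusion].
#' @param file output PDB path.
#' @return `file`, invisibly.
#' @export
write_toy_trajectory <- function(traj, file) {
  nf <- dim(traj$positions)[1]; nl <- dim(traj$positions)[2]
  xyz <- matrix(NA_real_, nf, 3 * nl)
  for (k in 1:3) xyz[, seq(k, by = 3, length.out = nl)] <-
    nm_to_ang(traj$positions[, , k])
  bio3d::write.pdb(file = file, xyz = xyz,
                   type = rep("HETATM", nl),
                   eleno = seq_len(nl), elety = rep("C1", nl),
                   resid = rep("LIG", nl), resno = seq_len(nl),
                   chain = rep("A", nl))
  edge <- nm_to_ang(traj$system$box_edge)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                   edge, edge, edge, 90, 90, 90)
  writeLines(c(cryst, readLines(file)), file)
  gt <- list(events = traj$events, times = traj$times, seed = traj$seed,
             box_edge_nm = traj$system$box_edge)
  jsonlite::write_json(gt, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read back a toy trajectory written by [write_toy_trajectory()]
#'
#' @param file PDB path (the `<file>.json` sidecar must sit next to it).
#' @param system the [toy_system()] that generated it.
#' @return a `toy_trajectory` (positions in nm).
#' @export
read_toy_trajectory <- function(file, system) {
  md <- read_md_trajectory(file)
  gt <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  nf <- dim(md$xyz)[1]; nl <- dim(md$xyz)[2]
  pos <- array(ang_to_nm(md$xyz), dim = c(nf, nl, 3))
  ev <- as.data.frame(gt$events)
  if (nrow(ev) == 0)
    ev <- data.frame(ligand = integer(0), type = character(0),
                     frame = integer(0), channel = integer(0))
  structure(list(positions = pos, events = ev, system = system,
                 times = as.numeric(gt$times), seed = gt$seed),
            class = "toy_trajectory")
}
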