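# Fixtures built in code: small systems, hand-made trajectories and series.

# default toy system but with an exactly symmetric pair of channels
symmetric_toy_system <- function(radius = 0.45) {
  toy_system(channels = list(list(axis = c(0, 0, 1), radius = radius),
                             list(axis = c(0, 0, -1), radius = radius)))
}

# construct an md_trajectory directly from coordinates.
# xyz: array [frame x atom x 3] (Angstrom); atoms: minimal atom table.
make_md_trajectory <- function(xyz, elety, box = NULL, dt = 1,
                               resno = seq_along(elety),
                               resid = rep("ALA", length(elety))) {
  atoms <- data.frame(type = "ATOM", eleno = seq_along(elety),
                      elety = elety, resid = resid, chain = "A",
                      resno = resno, stringsAsFactors = FALSE)
  structure(list(xyz = xyz, atoms = atoms, box = box,
                 times = (seq_len(dim(xyz)[1]) - 1) * dt),
            class = "md_trajectory")
}

# a state_series built from a label string like "UUIBBIU" (dt in ns);
# com/surface_dist laid out so that bound frames are inside the surface
# and unbound frames outside it
make_label_series <- function(labels_chr, dt = 1, contact_cutoff = 4) {
  lab <- c(U = "unbound", I = "intermediate", B = "bound")[
    strsplit(labels_chr, "")[[1]]]
  n <- length(lab)
  sdist <- ifelse(lab == "unbound", contact_cutoff + 2,
                  ifelse(lab == "intermediate", 1, -6))
  com <- cbind(seq_len(n), 0, 0)
  umdkin:::.new_state_series(ligand = 1L, labels = unname(lab),
                             frame_times = (seq_len(n) - 1) * dt,
                             com = com, surface_dist = sdist,
                             contact_cutoff = contact_cutoff)
}

# random irreducible row-stochastic matrix
random_stochastic <- function(k) {
  m <- matrix(stats::runif(k * k, min = 0.05, max = 1), k, k)
  m / rowSums(m)
}
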