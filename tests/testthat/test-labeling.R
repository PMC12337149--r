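# Hand-built three-atom topology: two metal anchors 2 A apart on x, plus a
# far protein atom; one single-atom ligand moved between frames. All
# distances below are checked against hand-computed values.
make_site_fixture <- function(lig_pos) {
  nf <- nrow(lig_pos)
  xyz <- array(NA_real_, c(nf, 4, 3))
  for (f in seq_len(nf)) {
    xyz[f, 1, ] <- c(-1, 0, 0)       # anchor 1 (Ni)
    xyz[f, 2, ] <- c(1, 0, 0)        # anchor 2 (Fe)
    xyz[f, 3, ] <- c(30, 0, 0)       # distant protein atom
    xyz[f, 4, ] <- lig_pos[f, ]      # ligand
  }
  make_md_trajectory(xyz, elety = c("NI", "FE", "CA", "C1"),
                     box = c(200, 200, 200))
}

test_that("frame labels follow the geometric bound/unbound criteria", {
  # site COM at origin (NI/FE nearly equal mass), anchor midpoint at origin
  lig <- rbind(c(0, 0, 0),      # at site COM and midpoint -> bound
               c(0.5, 3.8, 0),  # near site, in contact, > interface cutoff
               c(0, 100, 0),    # no contact within 4 A -> unbound
               c(0, 2, 0))      # inside both cutoffs -> bound
  traj <- make_site_fixture(lig)
  site <- site_definition(site_atoms = 1:2,
                          anchor_pair = list(1L, 2L),
                          bound_cutoff = 5, interface_cutoff = 3)
  series <- label_frames(traj, site, contact_cutoff = 4,
                         ligands = list(4L))
  expect_length(series, 1)
  expect_identical(series[[1]]$labels,
                   c("bound", "intermediate", "unbound", "bound"))
  # surface distance at frame 1 equals distance to the nearest anchor
  expect_equal(series[[1]]$surface_dist[1], 1)
  expect_equal(series[[1]]$surface_dist[3], sqrt(1 + 100^2))
})

test_that("labelling uses the minimum-image convention", {
  # ligand across the periodic boundary: 199 A apart in-box, 1 A wrapped
  nf <- 1
  xyz <- array(NA_real_, c(1, 2, 3))
  xyz[1, 1, ] <- c(0.5, 0, 0)
  xyz[1, 2, ] <- c(199.5, 0, 0)
  traj <- make_md_trajectory(xyz, elety = c("FE", "C1"),
                             box = c(200, 200, 200))
  site <- site_definition(1L, list(1L, 1L), bound_cutoff = 5,
                          interface_cutoff = 3)
  series <- label_frames(traj, site, ligands = list(2L))
  expect_identical(series[[1]]$labels, "bound")
})

test_that("empty selections are configuration errors", {
  expect_error(site_definition(integer(0), list(1L, 2L)), "empty")
  traj <- make_site_fixture(rbind(c(0, 0, 0)))
  site <- site_definition(1:2, list(1L, 2L))
  expect_error(label_frames(traj, site, ligands = list()), "empty")
})

test_that("a hand-traceable label series yields one binding and one unbinding", {
  s <- make_label_series("UUIBBIU", dt = 1)
  ev <- extract_events(s, min_dwell = 1)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$type, c("binding", "unbinding"))
  expect_equal(ev$passage_time[1], 3)   # FPT from frame 0 to first B
  expect_equal(ev$passage_time[2], 3)   # residence from B to U
})

test_that("all-unbound and all-intermediate series yield no events", {
  expect_identical(nrow(extract_events(make_label_series("UUUUUU"))), 0L)
  expect_identical(nrow(extract_events(make_label_series("IIIIII"))), 0L)
})

test_that("later FPTs are referenced to the preceding unbinding", {
  s <- make_label_series("UBBUUBU", dt = 1)
  ev <- extract_events(s, fpt_from = "previous_unbinding")
  expect_identical(ev$type, c("binding", "unbinding", "binding",
                              "unbinding"))
  expect_equal(ev$passage_time[3], 2)   # frames 4 -> 6
  ev2 <- extract_events(s, fpt_from = "replica_start")
  expect_equal(ev2$passage_time[3], 5)  # frames 1 -> 6
})

test_that("min_dwell suppresses short recrossings", {
  s <- make_label_series("UUUBUBBBUUU")
  expect_identical(nrow(extract_events(s, min_dwell = 1)), 4L)
  ev <- extract_events(s, min_dwell = 2)
  expect_identical(ev$type, c("binding", "unbinding"))
  expect_identical(ev$end_frame, c(6L, 9L))
})

test_that("events alternate and counts differ by at most one", {
  set.seed(41)
  for (rep in 1:20) {
    lab <- paste(sample(c("U", "I", "B"), 200, TRUE,
                        prob = c(0.4, 0.2, 0.4)), collapse = "")
    ev <- extract_events(make_label_series(lab),
                         min_dwell = sample(1:3, 1))
    if (nrow(ev) == 0) next
    expect_true(all(ev$type[c(TRUE, FALSE)] == "binding"))
    types <- table(factor(ev$type, c("binding", "unbinding")))
    expect_lte(abs(types[1] - types[2]), 1)
    expect_true(all(diff(ev$end_frame) > 0))
  }
})

test_that("raising min_dwell never increases the event count", {
  set.seed(42)
  for (rep in 1:10) {
    lab <- paste(sample(c("U", "I", "B"), 300, TRUE), collapse = "")
    s <- make_label_series(lab)
    n <- vapply(1:4, function(md) nrow(extract_events(s, min_dwell = md)),
                integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("raising the bound cutoff never loses bound frames", {
  traj <- simulate_ligand_diffusion(toy_system(), 6, 2000, seed = 13)
  n_bound <- vapply(c(4, 5, 6, 8), function(bc) {
    site <- site_definition(1L, list(1L, 1L), bound_cutoff = bc)
    series <- label_frames(traj, site)
    sum(vapply(series, function(s) sum(s$labels == "bound"), integer(1)))
  }, integer(1))
  expect_true(all(diff(n_bound) >= 0))
})

test_that("hysteresis-free extraction equals the naive transition count", {
  set.seed(43)
  for (rep in 1:10) {
    lab <- paste(sample(c("U", "B"), 150, TRUE), collapse = "")
    s <- make_label_series(lab)
    ev <- extract_events(s, min_dwell = 1)
    v <- strsplit(lab, "")[[1]]
    naive_bind <- sum(v[-1] == "B" & v[-length(v)] == "U")
    # the first frame counts as unbound reference
    if (v[1] == "B") naive_bind <- naive_bind + 1
    expect_identical(sum(ev$type == "binding"), as.integer(naive_bind))
  }
})

test_that("extracted events reproduce the generator's ground truth", {
  sys <- toy_system()
  for (s in c(101, 102)) {
    traj <- simulate_ligand_diffusion(sys, 9, 8000, seed = s)
    ev <- extract_events(label_frames(traj))
    expect_identical(nrow(ev), nrow(traj$events))
    expect_identical(ev$type, traj$events$type)
    expect_identical(ev$ligand, as.integer(traj$events$ligand))
    expect_true(all(abs(ev$end_frame - traj$events$frame) <= 1))
  }
})

test_that("surface crossing points behave per the trace geometry", {
  # monotone inward trace: last outside point is returned
  s <- make_label_series("UUIBB")
  ev <- extract_events(s)
  cp <- surface_crossing_point(ev, 1)
  expect_true(cp$crossing)
  expect_identical(cp$frame, 2L)   # last unbound frame before entry
  expect_equal(cp$point, c(2, 0, 0))
  # trace never crossing the surface: flagged, excluded from assignment
  s2 <- make_label_series("IIIBB")
  ev2 <- extract_events(s2)
  cp2 <- surface_crossing_point(ev2, 1)
  expect_false(cp2$crossing)
  tun <- toy_tunnels(toy_system())
  expect_warning(a <- assign_events(ev2, tun), "no surface crossing")
  expect_true(is.na(a))
})

test_that("event tables round-trip through CSV without the traces", {
  s <- make_label_series("UUIBBIU")
  ev <- extract_events(s)
  f <- tempfile(fileext = ".csv")
  write_events_csv(ev, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 2L)
  expect_equal(back$passage_time, ev$passage_time)
})
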