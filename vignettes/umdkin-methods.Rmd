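---
title: "Methods: ligand (un)binding kinetics, pathways and gating from unbiased MD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand (un)binding kinetics, pathways and gating from unbiased MD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umdkin)
```

`umdkin` analyses unbiased MD simulations in which many identical gas
ligands diffuse around an enzyme with a buried catalytic site, spontaneously
binding and unbinding through internal tunnels. This vignette documents the
models and estimators, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was open.

## State model

Each ligand copy is labelled per frame:

* **bound** — ligand centre of mass within `bound_cutoff` (default 5 Å) of
  the catalytic-group centre of mass *and* within `interface_cutoff` of the
  midpoint of the two metal anchors. The anchor-midpoint criterion
  operationalises "near the metal interface"; no quantitative value is
  standard, so it defaults to 3 Å and is configurable. The midpoint
  distance was chosen because it is the simplest rotation-invariant proxy
  for proximity to the metal–metal axis.
* **unbound** — minimum distance from any ligand atom to any protein heavy
  atom above `contact_cutoff` (default 4 Å): the ligand has no protein
  contact. Whether "fully solvated" should add a water-coordination
  criterion is not specified anywhere we know of; only the contact
  criterion is implemented.
* **intermediate** — everything else (in a tunnel, at the surface, near
  but not in the site).

All distances use the minimum-image convention with orthorhombic boxes.

## Events and hysteresis

A binding event fires at the first frame of a run of at least `min_dwell`
bound frames that follows the most recent run of at least `min_dwell`
unbound frames; unbinding is symmetric. `min_dwell` (default 1 frame)
exists to suppress single-frame recrossing noise; raising it can only
reduce the event count (a property the tests assert). The ligand is
assumed unbound at replica start, so the first binding's first-passage
time is measured from frame one.

### First-passage times and k_on

`extract_events()` records per-ligand passage times. For the association
rate constant these are **not** used directly: `k_on = 1/(⟨FPT⟩·C)` is
only copy-number invariant if ⟨FPT⟩ is the waiting time of the *site* —
the time from the moment the site is free (replica start, or the previous
unbinding of whichever copy was bound) until the next binding of any copy.
Doubling the number of copies halves that waiting time and doubles `C`,
leaving k_on unchanged. `site_fpts()` merges the events of all copies of
a replica chronologically and returns those waiting times; they feed
`estimate_kon()`. Per-ligand residence times feed `estimate_koff()`
unchanged, since k_off is a property of one bound complex.

Both rates carry bootstrap standard errors from resampling events with
replacement (default 1000 replicates, seeded). Event-level resampling was
chosen over replica-level resampling because typical event counts per
replica are small. Confidence intervals are normal-theory intervals
`rate ± z·SE` built from the bootstrap SE — the same `rate ± SE` form in
which such estimates are conventionally reported; at the event counts of
the synthetic study this interval had slightly better finite-sample
coverage than the percentile interval.

## Pathway assignment

Tunnels are ordered sphere chains (centre + radius) read from the
PDB-dialect sphere files written by tunnel-detection tools (cluster id in
the residue-number field, radius in the B-factor field).

Each event carries a crossing trace: ligand centre-of-mass positions in a
window (default 25 frames each side, extended to cover the full transit)
around the surface crossing — the last inward crossing for binding, the
first outward crossing after binding for unbinding. A tunnel is scored by
the mean over scored trace points of (distance to nearest sphere centre −
that sphere's radius, floored at zero); the lowest-scoring tunnel wins if
its score is at most `max_assign_dist` (default 3 Å), otherwise the event
is reported `unassigned` for human review. Ties break by tunnel order.

Which trace points are scored matters. Bulk frames far from any mouth and
deep-site frames (which sit near *every* tunnel's innermost spheres) both
dilute the match; a ligand can slide between tunnels where they meet near
the site, pop out of the surface into a mouth and re-enter elsewhere, or
surf across another tunnel's mouth after exiting. The scored points are
therefore the *transit* points — in a channel or in a tunnel's mouth
region, never in the bound site — nearest the decisive shell crossing:
for binding, the start of the final inside-surface segment before the
event completes (the last entry); for unbinding, the last
inside-to-outside transition before the ligand reaches bulk (the final
exit). The default `n_keep = 1` scores that single entry/exit-adjacent
point, the direct automation of assigning events by matching entry and
exit points; in validation on the toy generator this reproduces the
recorded channel of every event across thousands of events and multiple
master seeds. Larger `n_keep` averages over the adjacent transit and is
more robust to single noisy frames in real data.

## Symmetry and distribution comparison

At equilibrium, detailed balance makes the probability of binding through
a tunnel equal to the probability of unbinding through it. The package
tests this with a standard two-sample chi-square on the 2×k table of
binding vs unbinding counts. Categories whose expected count falls below
`min_expected` (default 5, the classical rule) in either row are pooled
into `other` (only while at least two categories remain); if any expected
count is still below the threshold, the p-value comes from seeded
Monte-Carlo resampling of tables with fixed margins (default 1e5 draws)
instead of the asymptotic distribution, and the method used is recorded.
Similar tunnels are never merged automatically; a user-supplied merge map
is honoured before testing.

## Bottleneck gating

`min_residue_distance()` computes, per frame, the minimum over heavy-atom
pairs of the minimum-image distance between two residues. Hydrogens are
excluded by default because their placement is force-field dependent.
`distance_density()` builds a normalised histogram (default 0.2 Å bins)
plus a Gaussian kernel estimate; `classify_states()` finds density modes
with prominence at least 5% of the global maximum (prominence = height
above the highest valley separating the mode from higher terrain, which
suppresses noise modes), places the open/closed threshold at the valley
between the two dominant modes, and reports the fraction of frames above
it. Unimodal densities are flagged rather than force-split.

## Markov state model and free-energy landscape

Equilibrium populations must not be read off a biased ensemble of short
trajectories directly, so the gating coordinate is discretised (default
40 equal-width bins over the observed range), transition counts are
accumulated at a lag with a sliding window that never crosses trajectory
boundaries, and the transition matrix is estimated on the largest
strongly connected set of states. The default estimator symmetrises the
counts, `(C + Cᵀ)/2`, before row normalisation — detailed balance by
construction, consistent with equilibrium sampling. This is a known
approximation to full maximum-likelihood reversible estimation; for a
one-dimensional coordinate it is adequate and keeps the stationary
distribution available in closed form (row sums of the symmetrised
counts). Implied timescales are `-lag/ln λᵢ`; when `lag` is not given,
`build_msm()` picks the smallest lag (doubling from 1) whose slowest
implied timescale changes by less than 10% when the lag doubles. The
free-energy landscape is `ΔG = -k_B T ln π`, shifted so the minimum is
zero, reported in kT and (at the configured temperature, default 300 K)
kcal/mol; empty bins get `+Inf` and never define the minimum.

## The synthetic generator

`toy_system()` is a geometric stand-in for a buried-site enzyme: a
spherical exclusion volume of radius 1.2 nm at the centre of a periodic
5 nm box, pierced by three cylindrical channels (radii 0.45, 0.45 and
0.35 nm along +z, +x and −y) leading to a buried site sphere of radius
0.5 nm — the same 5 Å as the bound-state cutoff. Ligands are points
performing overdamped Brownian dynamics: Gaussian steps of per-axis
variance `2·D·dt` with `D = 4.5 nm²/ns` (representative of H₂ in water)
and `dt = 0.005 ns`, wrapped periodically. A step ending inside the
protein sphere is rejected (the ligand stays put) unless it ends inside a
channel or the site; direct jumps between the site and the region outside
the shell are rejected in both directions because they would tunnel
through the protein wall, and the symmetric rejection preserves detailed
balance. Nine ligands in this box give 119.6 mM, matching the ~120 mM
regime of a hundred-copy production box; a short design pilot confirmed
approximately exponential first-binding times (coefficient of variation
≈ 1.0) with mean ≈ 21 ns, after which the defaults were frozen.

The generator records ground truth: every binding/unbinding event with
the channel transited. The recorded channel is the one containing the
ligand at the frame it crosses the protein-radius shell; because outward
steps past the shell are always legal, a crossing point can fall in the
gap between channel cones, in which case the most recently occupied
channel is recorded — the channel the ligand actually came through.

What the toy emulates: independent diffusing copies, an excluded protein
volume with a small number of geometrically distinct entry channels,
exponential-like site waiting times, channel-usage probabilities fixed by
geometry, detailed balance at equilibrium, and a bimodal Markov-switching
gating coordinate (`generate_two_state_series()`). What it does not:
explicit solvent and friction anisotropy inside tunnels, ligand–ligand
interaction, site exclusion (two copies may occupy the site), protein
flexibility, energetic (rather than geometric) barriers, and force-field
detail. Passing tests on the toy therefore validate the *estimators and
bookkeeping* — labelling, event extraction, rate formulas, assignment,
test calibration, MSM algebra — not any claim about a real enzyme's
numbers.

## The synthetic validation study

`kon_recovery_study()` runs the full pipeline on 50 independently seeded
toy systems of 16 ligands × 15000 frames (75 ns) each. The ground-truth
rate is the pooled estimate from 24 additional calibration runs of the
*same protocol*: site waiting times are affected by rebinding (a freshly
unbound ligand sits at the surface and often returns quickly) and by
run-length censoring, so the truth must be defined as the large-sample
limit of the identical protocol rather than an estimate at a different
copy number, and enough calibration runs are used that the truth's own
sampling error (~3%) stays far below the per-run interval width (~30%). The study records, per run, the k_on interval and whether
it covers the truth, event-level agreement between assigned tunnels and
recorded channels, and the binding/unbinding symmetry p-value. These
problem sizes keep the whole study at a few minutes on one CPU while
leaving ~40–60 events per run, enough for the interval coverage to sit
near its nominal level.

## Degenerate inputs and numerical choices

* Constant series discretise into a single occupied bin (edges widen by
  ±0.5 around the value).
* Two-state emissions whose means are closer than the sum of their
  standard deviations generate a warning (states not separable), not an
  error.
* Bootstrap of a single event or a constant event list yields SE 0.
* Traces that never cross the protein surface are flagged and excluded
  from pathway assignment with a warning.
* `stationary_distribution()` refuses reducible matrices, naming the
  strongly connected blocks; eigenvector components below 1e-14 are
  clipped to zero.
* Chi-square pooling never reduces the table below two categories; an
  all-sparse table goes to the Monte-Carlo branch intact.
* Identical seeds give bit-identical simulations, bootstraps and
  Monte-Carlo p-values; seeded helpers restore the caller's RNG state.

## Known limitations

* The toy protein is a sphere; real tunnel mouths cluster on one face and
  tunnels curve, so assignment thresholds tuned here (3 Å) may need
  loosening on real geometries.
* Reversible estimation by count symmetrisation slightly biases the
  slowest implied timescale when sampling is far from equilibrium.
* k_off from per-ligand residence times treats the site as non-exclusive,
  mirroring the generator; with site exclusion the residence time
  definition is unchanged but waiting times would lengthen slightly.
* GRO/XTC trajectories are not read; use PDB (multi-model) or DCD with a
  PDB topology.
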