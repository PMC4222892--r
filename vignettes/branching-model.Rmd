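---
title: "A reaction-diffusion model of compound-leaf branching on a growing margin ring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion model of compound-leaf branching on a growing margin ring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringleaf)
```

## The model

Compound leaves such as those of the semi-aquatic crucifer *Rorippa
aquatica* build their branched shape by iteratively adding leaflet
primordia to a growing leaf margin. `ringleaf` simulates this process by
treating the margin as a closed polygon of segments ("cells"), each one a
single compartment of a one-dimensional reaction–diffusion (RD) system,
and deforming the polygon by boundary propagation coupled to the RD
pattern.

**Reaction–diffusion kinetics.** The reactants are an activator $u$ and an
inhibitor $v$ with bounded-linear-synthesis kinetics:

$$
\frac{\partial u}{\partial t}
  = \operatorname{clamp}(a u + b v + c,\, 0,\, S_u) - \mu_u u
  + D_u \nabla^2 u, \qquad
\frac{\partial v}{\partial t}
  = \operatorname{clamp}(d u + e v + f,\, 0,\, S_v) - \mu_v v
  + D_v \nabla^2 v .
$$

Synthesis is linear in both reactants, clamped to $[0, S]$; decay is
first-order and always active; the clamps are the only nonlinearity and
set the pattern amplitude. With an autocatalytic activator
($a > \mu_u$), inhibition of the activator ($b < 0$), cross-activation of
the inhibitor ($d > 0$) and a much faster-diffusing inhibitor
($D_v \gg D_u$), the homogeneous steady state is stable to uniform
perturbations but unstable to a band of spatial modes — a Turing
(diffusion-driven) instability producing a stationary periodic pattern of
activator peaks. `dispersion_relation()` gives the linear growth rate of
each discrete ring mode analytically and serves as the oracle for this
regime throughout the tests.

**Boundary propagation.** Each vertex of the margin polygon moves along
the renormalized sum of the outward unit normals of its two adjacent
cells. The sum's magnitude is discarded deliberately, so that the speed is
controlled solely by the reactant law — this keeps "growth rate
proportional to concentration" literally true at corners. Two velocity
laws are provided:

* **expansion** — speed $= k_g \bar r$, with $\bar r$ the mean of the
  selected reactant over the vertex's two cells: growth is concentrated
  under activator peaks;
* **inhibition** — speed $= \max(0, g_0 - k_h \bar r)$: a constant base
  expansion suppressed under the pattern, so the troughs bulge outward.
  The clamp at zero forbids margin retraction, which is never observed.

A cell longer than `L_div` divides at its midpoint; both daughters
inherit the mother's $(u, v)$ exactly, at most one division per cell per
growth step. The polygon may self-intersect as branches cross; crossings
are never repaired, since the real organ resolves them in the third
dimension. Area-based invariants are therefore only asserted on convex
test fixtures.

**Compartment coupling.** The default `coupling_mode = "topological"`
treats every cell as one RD compartment at unit spacing regardless of its
geometric length, because domain growth is realized by cell division: a
region of the margin gains RD "space" exactly when its cells divide. A
conservative finite-volume `"metric"` mode (inter-cell spacing
$(\ell_i + \ell_j)/2$, division by $\ell_i$, exact flux conservation) is
kept for sensitivity checks.

**Integration.** Explicit forward Euler with an enforced stability bound
$dt \le 2 / (4 \max(D_u, D_v) + \max(\mu_u, \mu_v))$ (unit spacing), many
RD substeps per growth step so the pattern relaxes faster than the domain
deforms. Negative concentrations produced by a step are clipped to zero
and counted in the run's warning counters; the clamped synthesis makes
this rare. The initial condition — a regular ring of six cells with
uniform random reactant perturbations around the steady state — is the
only stochastic element, so a trajectory is a pure function of
`(config, seed)`.

## The two calibrated regimes

The published account of this model family states the kinetic form only
qualitatively, so the package ships two parameter sets calibrated with
its own tools (`classify_behavior()` over seeded runs, frozen in
`inst/extdata/`):

```{r}
insertion_config()$rd
splitting_config()$rd
```

The two sets share the same linearization — identical Jacobian, decay and
diffusion, hence the same dispersion relation with a stable uniform mode
and one unstable band around mode wavelength of roughly ten cells — and
differ only in the activator saturation ceiling `S_u` and the growth law:

* **Insertion regime** (`S_u = 0.5`, expansion mode): synthesis rarely
  saturates, peaks are tall spikes (amplitude $\approx S_u/\mu_u = 5$)
  that resist widening. Growth under the peaks stretches the flanks;
  gaps between peaks widen until a new peak nucleates mid-gap. Seeded
  runs from the 6-cell ring double their peak count through insertion:
  1, 2, 4, 8, 16.
* **Splitting regime** (`S_u = 0.12`, inhibition mode with
  $g_0 = 0.02$, $k_h = 0.015$): synthesis saturates just above the
  steady state, peaks are low plateaus (amplitude $\approx 1.2$). The
  margin grows fastest in the troughs, which bulge outward; stretched
  plateaus widen into the growing regions and pinch into two. The same
  doubling cascade emerges, now by splitting.

The qualitative control knob matches the classical picture: weakly
saturated ("spot-forming") kinetics insert, strongly saturated
("stripe-forming") kinetics split. Calibration used five seeds per
regime; across them, essentially all classified doubling events are
insertions in the first regime and over nine in ten are splittings in
the second.

**Selectable inhibiting reactant.** The velocity laws default to the
activator $u$ in both modes (it is what the pattern plots threshold);
`reactant_select = "v"` is available since either choice is defensible
for the inhibition law.

## Morphometrics

`detect_peaks()` finds strict local maxima of $u$ in cyclic order with a
topographic-prominence filter (default 0.1 concentration units; exact
plateaus resolve to the lowest cell index). `build_genealogy()` tracks
peak identities across snapshots by nearest normalized-arc matching and
classifies each birth:

* a new peak in the **interior third** of the gap between two persisting
  peaks is an *insertion*;
* a new peak in an outer third, beside a persisting peak that shifts away
  as the pair separates, is a *splitting* (the nearer flank is its
  parent);
* a birth with no persisting peak to measure against is *ambiguous*.

Two tracking refinements matter in practice, both visible in the unit
tests. First, the match radius is `min(max_match_shift, 0.35/n_peaks)`:
early in a run, normalized positions jump by several percent whenever a
small ring divides, so the radius must be generous (default 0.1); once
dozens of peaks crowd the ring a fixed radius would span whole gaps, so
it tightens with the peak count. Second, a peak whose prominence flickers
across the threshold would otherwise die and be reborn as a spurious new
identity; a disappearance is therefore cancelled if a matching peak
reappears within a grace window (5 snapshots), and a lone peak — which
cannot change identity — always reclaims its record.

`doubling_events()` reduces the per-snapshot peak counts to plateaus that
persist at least `min_run = 10` snapshots. In the calibration runs,
genuine inter-event plateaus persist for 23 or more snapshots while
mid-wave pauses last at most 6, so the default separates them with an
order-of-magnitude margin.

`assign_branch_orders()` rebuilds the axis hierarchy: the first-emerged
peak is the terminal leaflet capping the main (proximodistal) axis; its
first partner is the base of the primordium (on the main axis, excluded
from leaflet counts); every later peak founds an axis attached to the
axis owning the **older** of its two flanking peaks at birth. This
older-flank rule is a reconstruction — the narrated sequence (two
primaries at the second event, four new primaries per event thereafter,
first secondaries on the oldest primaries at the fourth event) does not
state an algorithm — and it is validated against the combinatorial model
below, which it reproduces exactly.

## The ideal insertion model and its closed forms

`ideal_insertion_tree()` is the purely combinatorial abstraction: one
peak; event 1 adds its antipode (the base); every later event inserts a
peak at the midpoint of every gap, each attaching to its older flank's
axis. This generative process is the single source of truth for the
closed forms, which are validated against it by exact integer equality
for all $n \le 12$ rather than transcribed:

* total leaflets $T_n = 2^n - 1$ (all $2^n$ peaks minus the base);
* primary leaflets $P_1 = 0$, $P_2 = 2$, $P_n = P_{n-1} + 4$, i.e.
  $P_n = 4n - 6$;
* per-primary secondary profiles (`secondary_profile()`), reported in
  half-leaf order (the leaf is treated as symmetric about the
  proximodistal axis), satisfying the partition identity
  $1 + \sum_{\text{primaries}} (1 + \text{subtree}) = T_n$.

A lone initial peak counts as zero leaflets ($T_0 = 0$): before the base
exists there is nothing to oppose the future terminal, which becomes a
countable leaflet at the first event.

## What the tests do and do not show

The simulations behind the packaged checks use the frozen configurations:
1200 growth steps × 25 RD substeps for the insertion regime and 1700 for
the splitting regime (a few seconds per seed), five calibration seeds per
regime, and a 200-cell fixed ring for the mode-selection experiment.
These sizes were chosen so a run comfortably completes four doubling
events — the regime the combinatorial theory describes — before
interactions between crowded branches complicate the geometry.

The onset experiment (`fixed_ring_peak_count()`) integrates from a small
perturbation (amplitude 0.01) only until the activator deviation first
reaches the steady-state value, then counts peaks. At that point the
dynamics are still governed by the linearization, so the count is
comparable to the dispersion argmax; integrating much longer instead
measures nonlinear coarsening, which in this model selects a slightly
longer wavelength. The splitting-regime check aggregates the event
fractions over the five seeds (the stabler statistic than per-seed
fractions) and verifies that the outermost margin bulge of every run
sits at a low activator quantile.

Passing these checks shows that the mechanism — a periodic pattern
iteratively doubled on a pattern-coupled growing boundary — reproduces
the regular, nested, synchronous branching of the combinatorial model.
It does not show fidelity to real leaves beyond that: the real organ
branches asynchronously (apically biased, which would need an
anisotropic growth tensor — out of scope), its leaflet counts plateau as
the leaf matures (the ideal model runs a fixed event count instead), and
the molecular identity of the reactants is unknown. The synthetic-data
generator emulates seeded random initial conditions on a tiny ring; it
does not emulate measurement noise, cell-size variability, or
three-dimensional structure.

## Numerical and design choices

* Winding and normals: counterclockwise winding is canonical and
  enforced at construction; a cell's outward normal is its direction
  rotated by −90°. Exactly antiparallel adjacent normals (a folded
  vertex) fall back to the longer cell's normal and are counted.
* Division splits at the midpoint — the symmetric choice, stated once.
* The 80 % majority threshold in `classify_behavior()` labels a regime;
  below it the run is `irregular`.
* Configuration files are YAML; unknown keys are rejected by name and a
  `dt_rd` above the stability bound is refused with the bound printed.
* Trajectory CSVs print floats with 9 significant digits and round-trip
  through the reader bit-identically on rewrite.
* `run_simulation()` stops cleanly at `max_cells` to bound memory; all
  packaged runs finish their doubling cascade well before the cap.

## A minimal session

```{r, eval = FALSE}
cfg <- insertion_config()
traj <- run_simulation(cfg, seed = 1)
gen <- build_genealogy(traj)
doubling_events(gen)
leaflet_count_series(gen)
autoplot(kymograph(traj))        # space-time plot of the activator
plot_peak_counts(gen)            # the doubling staircase
glance(ideal_insertion_tree(6))  # the combinatorial prediction
```
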