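---
title: "Methods: quantifying lipid scrambling with scramblekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lipid scrambling with scramblekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblekit)
options(scramblekit.quiet = TRUE)
```

## The problem

Phospholipid flip-flop — the translocation of a lipid between bilayer
leaflets — is extremely slow in a protein-free membrane because the polar
headgroup must cross the hydrophobic core. Scramblases catalyse it,
typically by offering a polar crevice through which the headgroup slides
while the acyl chains stay in the membrane (the "credit card" mechanism).
The Sec61 translocon and the translocon-associated protein (TRAP) complex
are such scramblases at the endoplasmic reticulum. scramblekit packages
the analyses needed to quantify this activity from coarse-grained
molecular-dynamics trajectories and from fluorescence scrambling assays:
event detection and rate statistics, density-based free-energy profiles
with entropy/enthalpy decomposition, Arrhenius/Eyring kinetics, membrane
thickness and volumetric density maps, and a forward model plus fitting
machinery for dithionite and BSA assay curves. A synthetic-data generator
with known ground truth makes every stage testable without any simulation
data.

Units are fixed package-wide: nm, ns, K, kJ/mol; scrambling rates in
events per microsecond (1/µs); assay time in seconds.

## Flip-flop detection

A lipid's orientation is read from the transverse separation of two
beads: the headgroup phosphate (Martini "PO4") and the terminal acyl
bead ("C4B"), `dz = z_head − z_tail`. With threshold `d` (default
2.1 nm), `dz ≥ +d` is the upper-leaflet orientation, `dz ≤ −d` the
lower, and anything in between is undetermined. The default follows the
working range in which detected event counts plateau for coarse-grained
phospholipids (roughly 1.8–2.6 nm on clean synthetic data;
`threshold_scan()` reports the plateau for any data set).

Two deliberate choices:

* **Sign convention.** We use the physically natural orientation
  (head above tail ⇒ upper leaflet). Some descriptions of this
  criterion in the literature read with the opposite sign; since event
  *counting* is invariant to the convention, `assign_leaflets()` exposes
  `leaflet_sign` for users who need the mirrored labelling.
* **Hysteresis.** The *assigned* leaflet changes only when the
  instantaneous orientation fully reaches the opposite threshold.
  A lipid that dwells near the midplane, or briefly becomes
  undetermined, keeps its previous assignment. This prevents
  double-counting midplane excursions and makes consecutive events of
  one lipid alternate in direction by construction. One flip-flop is
  recorded per assignment change (`detect_events()`), timestamped at the
  first frame of the new assignment.

**Pathway attribution.** An event is attributed to a protein site
(Sec61, TRAP, …) when the head bead at the event frame lies within a
cutoff (default 2.0 nm) of the site's pathway beads, by minimum 3D
distance; otherwise it is "bulk". Ties break by distance and then site
name. "Initiation" is operationalized as the event frame because the
moment a lipid first commits to a flip is not observable at saved-frame
resolution.

**Lipid environment classes.** For thickness and composition statistics,
lipids are classed per frame as near a site (min head–protein distance
≤ 2 nm), bulk (≥ 3 nm from every site), or intermediate. The explicit
intermediate class exists because the 2 nm / 3 nm rules leave a gap;
the three classes partition each frame exactly.

## Rates and their statistics

`compute_rates()` treats the replica as the statistical unit: per (site,
lipid type), rate = mean over replicas of events/duration, with the SE
the replica sample SD over √n. Totals per site are sums over lipid
types, with the SE computed from per-replica totals. Zero-event cells
report `0.0 ± 0.0`.

Rate differences between two systems are tested with a Welch two-sample
t-test on per-replica rates (`compare_rates()`). The Welch form was
chosen because replica variances of different systems have no reason to
be equal; with typical replica counts (n = 5) the test is approximate,
and identical groups are defined to give p = 1.

## Arrhenius and Eyring analysis

`fit_arrhenius()` fits ln k against 1/T by ordinary least squares;
`E_A = −slope·R`. An inverse-relative-error weighted mode
(`weights = (k/se)²`, the delta-method weight for ln k) is available;
unweighted is the default because with ~5 temperature points weights
estimated from 5 replicas are themselves noisy.

Transition-state calculators: `eyring_rate()` gives
κ·(k_B·T/h)·exp(−G‡/RT) with κ = 1 by convention;
`eyring_speedup()` the fold acceleration exp((ΔG_ref − ΔG_new)/RT),
exactly the ratio of the Eyring rates; `scaled_half_life()` rescales a
measured reference half-life by that fold. The absolute Eyring prefactor
overestimates rates for diffusive barrier crossings, so the package uses
it only through ratios, where the prefactor cancels. A consistency check
connects the two routes: E_Arrh ≈ ΔH‡ + RT.

## Free-energy profiles

When flips are frequent (catalysed), the equilibrium headgroup density
ρ(z) samples the whole transverse coordinate and yields the free-energy
profile by Boltzmann inversion:

ΔG(z) = −RT ln(ρ(z)/ρ₀).

`density_profile()` histograms head-bead z into 300 slices spanning the
box height (the full box is used; a membrane-centred window would only
rescale ρ₀). Because the membrane fluctuates, z is measured relative to
the per-frame centroid of a protein reference group (e.g. a
transmembrane helix); profiles are invariant to rigid translations of
trajectory plus reference.

Choices in `boltzmann_invert()` / `barrier_height()`:

* ρ₀ is the maximum density, so the global minimum of ΔG is 0; when the
  two leaflet minima differ, the deeper one sets the zero.
* Zero-density bins map to +∞. If such bins are interior to the sampled
  region the profile is flagged `unsampled_core` and any barrier read
  from it is reported as a lower bound. We deliberately do not
  interpolate across unsampled cores: silent interpolation would
  fabricate barrier heights.
* The barrier is the maximum of ΔG between the two outermost minima
  (the leaflet equilibrium positions). Errors come either from the
  leaflet asymmetry (difference to the z-mirrored profile at the
  barrier; appropriate for single protein-free systems) or as the SD of
  per-replica barriers.

**Entropy/enthalpy decomposition.** `decompose_thermo()` uses the
finite-difference scheme with the entropy component assumed constant
across each temperature pair: for a pair (T₁, T₂),
ΔS(z) = −[ΔG(z,T₂) − ΔG(z,T₁)]/(T₂ − T₁) and
ΔH(z) = ΔG(z,T_mid) + T_mid·ΔS(z), evaluated at T_mid = 310 K with the
default pairs (300, 320) K and (290, 330) K. The reported profile is the
mean of the two pair estimates and the per-bin error their absolute
difference. The identity ΔG = ΔH + (−TΔS) holds pointwise at T_mid by
construction — it is a bookkeeping identity, not a validation. (Published
descriptions of this scheme vary between "constant entropy" and
"constant enthalpy" wording; the equations above are what is
implemented.) Profiles at different temperatures are linearly resampled
onto the T_mid grid, with a 1e-6 nm tolerance before resampling is
considered necessary.

**Thinning and the barrier.** `fit_thickness_barrier()` fits a
least-squares line through (membrane thickness, flip-flop barrier)
pairs — e.g. from simulations of lipids with different tail lengths —
and `predict_barrier_reduction()` evaluates the line at the bulk and the
locally thinned thickness; the difference of the intercepts along the
barrier axis estimates how much protein-induced thinning alone lowers
the barrier.

## Membrane maps

`thickness_map()` bins head beads into an xy grid (default 0.2 nm, the
coarse-grained bead scale) and takes thickness as the difference of the
per-cell leaflet mean z values. Leaflet means were preferred over
nearest-pair interleaflet distances because they are robust at low
per-cell counts; cells sampled by a single leaflet are undefined (`NA`),
never zero.

`volumetric_density()` histograms beads into cubic voxels (default
0.2 nm) in the reference-group frame and normalizes to number density;
the sum over voxels times voxel volume times frames equals the
observation count exactly, which the tests assert as a bookkeeping
invariant.

`pathway_continuity()` thresholds a density map, labels 26-connected
components, and reports whether one component touches both leaflet
planes — the operational definition of a continuous scrambling pathway.
The recommended threshold is ~10% of the bulk headgroup plateau density;
the verdict is monotone in the threshold (once broken, broken for all
higher thresholds), and the implementation is tested against an
independent queue-based flood fill.

## Assay model and fitting

The dithionite assay quenches NBD-labelled lipids in the outer leaflet
irreversibly (reduced labels go dark); the BSA back-extraction assay
quenches at most 50% of the fluorescence of the labels it can reach.
With symmetric 50/50 labelling the expected plateaus are:

| mode | no scrambling | complete scrambling |
|---|---|---|
| dithionite | 0.50 | 0.00 |
| BSA | 0.75 | 0.50 |

`simulate_assay()` integrates the minimal two-compartment mechanism that
reproduces all four endpoints:

dN_out/dt = k_scr(N_in − N_out) − k_q·N_out,
dN_in/dt = k_scr(N_out − N_in), dQ/dt = k_q·N_out,

with fluorescence F = N_out + N_in (+ 0.5·Q in BSA mode). Scrambling is
symmetric and bidirectional; quenching acts only on outer-accessible
label and only after the addition time; total label is conserved
exactly. The ODE system is integrated with a stiff solver (deSolve) at
tight tolerances. An optional non-scrambling vesicle fraction mixes in
protein-free vesicles; it is 0 by default. Experimental
protein-containing dithionite curves often level off around ~15% rather
than 0; part of that residual is attributed to slow dimming of the dye,
which this model does not attempt to describe — the 15% level is
therefore not a model prediction.

`normalize_and_trim()` divides by the mean pre-addition intensity, drops
pre-addition points and moves the origin to the addition time, so decays
start at (0, 1). `fit_double_exponential()` then fits
F(t) = F_s·exp(−t/τ_s) + F_f·exp(−t/τ_f) with F_s + F_f = 1 enforced
through the parameterization (logistic for the amplitude split,
log-scale decay times), Levenberg–Marquardt least squares, and
multi-start over five log-spaced decay-time initializations. Components
are ordered slow/fast on output. Fits in which the two decay times
coincide or one amplitude vanishes are flagged `degenerate`: the data
are then described by a single exponential and the component split is
arbitrary, so the flag is reported rather than penalized.

## The synthetic-data generator

`generate_trajectory()` emulates exactly the features the analyses rely
on, with known ground truth:

* head/tail bead pairs; head z Gaussian about its leaflet plane
  (±2.0 nm about the midplane, σ_z = 0.3 nm), tail on the midplane side
  with a 3.0 nm head–tail separation, in a 15 × 15 × 12 nm box —
  the scale of a coarse-grained translocon membrane patch;
* lateral diffusion as a per-frame Gaussian random walk (σ_xy = 0.1 nm
  per 10 ns frame), periodic in xy;
* flip-flop events drawn as a Poisson process at specified per-site
  system rates; a flipping lipid is placed laterally within 1 nm of its
  site centre and its mean transverse position crosses the membrane
  linearly over a 50 ns transit. The linear transit is the simplest
  path that exercises the hysteresis logic; if the lipid drawn for an
  event is still mid-transit the event is queued, never dropped;
* protein sites as static vertical bead columns (mirroring
  backbone-restrained proteins in the source simulations);
* an event log recording lipid, time, direction and true site.

Default trajectory sizes used throughout the tests — 600 lipids,
2000 frames at 10 ns spacing (20 µs) — were chosen to match the scale
of the replica simulations the rate statistics are designed for while
keeping a full five-replica recovery test in the tens of seconds.

Reproducibility: each generator call seeds R's global RNG stream via its
`seed` field (saving and restoring the caller's RNG state). A
counter-based per-lipid stream design was considered and rejected: base
R exposes a single stream, and the practical guarantee that matters —
identical spec ⇒ identical output — holds as is. Note that changing the
lipid count does change all draws.

What the generator deliberately does *not* emulate: force-field physics
(no energetics, no realistic transit paths), lateral phase behaviour,
protein internal motion, membrane undulations, and curvature. Passing
recovery tests therefore demonstrates the correctness of the estimators
(detection, attribution, rate statistics, inversion), not the realism of
any simulation; applying the package to real trajectories still requires
the usual convergence and sensitivity checks (`threshold_scan()`, replica
SEs, the mirror-asymmetry error).

`sample_from_pmf()` inverts a free-energy profile into transverse
samples by inverse-CDF on the profile grid (uniform within bins), which
makes the Boltzmann-inversion round trip exactly self-consistent up to
multinomial counting noise — the basis of the 20 kJ/mol barrier-recovery
test at 10⁶ samples.

## File formats and degenerate inputs

Text GRO (fixed-column, nm, multi-frame; 0.001 nm coordinate precision)
is the trajectory interchange format, with PDB (Å, converted on ingest)
accepted for single structures via bio3d. Binary XTC/TRR are not parsed:
no R-native reader exists, and conversion to GRO with standard tools is
lossless at the format's own stated precision. Only orthorhombic boxes
are supported; triclinic box lines raise an explicit unsupported-feature
error. Externally computed PMFs (e.g. AWH output) enter through the
XVG-style two-column reader and are treated identically to
density-derived profiles downstream.

Degenerate inputs are handled explicitly rather than silently: zero
densities (error if everywhere, +∞/flag otherwise), monotone profiles
(shape error in barrier extraction), single temperatures (error in the
Arrhenius series), zero-duration replicas (error), empty site bead sets
(configuration error), thresholds above the reachable separation
(warning plus zero counts).

## Known limitations

* Rates are event counts over replica time; no correction for
  unobserved fast recrossings below frame resolution.
* The environment classifier and site attribution use minimum distances
  to site beads, not solvent-accessible geometry.
* The assay forward model has two compartments only: no dithionite
  permeation, vesicle size distributions, inner-filter effects or
  photobleaching.
* The thickness map assumes the leaflet assignment is correct at frame
  resolution; during a transit a lipid briefly contributes to its
  departure leaflet.
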