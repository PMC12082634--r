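# scramblekit

Quantifying lipid scrambling by membrane proteins — such as the
Sec61/TRAP translocon of the endoplasmic reticulum — from
coarse-grained molecular-dynamics trajectories and fluorescence
scrambling assays.

Spontaneous lipid flip-flop between bilayer leaflets is blocked by a
free-energy barrier of roughly 60 kJ/mol, so in a protein-free membrane
it happens on the timescale of weeks. Scramblases lower that barrier by
tens of kJ/mol by letting the lipid headgroup slide through a polar
crevice while the tails stay in the membrane. scramblekit implements
the full analysis chain for measuring this catalysis:

* **Flip-flop detection** — a lipid's leaflet is read from the
  transverse head–tail bead separation Δz (threshold 2.1 nm) with a
  hysteresis criterion; one event per assigned-leaflet change. Events
  are attributed to a protein's scrambling pathway when they initiate
  within 2 nm of its pathway beads.
* **Rate statistics** — per-site, per-lipid-type rates (1/µs) with
  replica standard errors; Welch tests between systems; detection
  threshold sensitivity scans.
* **Kinetics** — Arrhenius fits of ln k vs 1/T
  (k = A·exp(−E_A/RT)); Eyring calculators
  k = κ(k_B T/h)·exp(−G‡/RT), barrier-change speed-up factors and
  half-life rescaling.
* **Free-energy profiles** — headgroup density ρ(z) in a protein-fixed
  frame (300 slices) inverted by ΔG(z) = −RT ln(ρ(z)/ρ₀); barrier
  extraction with leaflet-mirror or replica errors; entropy/enthalpy
  decomposition ΔS = −∂ΔG/∂T by finite differences over temperature
  pairs (300/320 and 290/330 K); thickness–barrier trend fits.
* **Membrane maps** — local interleaflet-distance thickness maps,
  lipid environment classification (near-site / intermediate / bulk),
  volumetric bead densities and scrambling-pathway continuity via
  26-connected components.
* **Assay kinetics** — a two-compartment forward model of the
  dithionite and BSA back-extraction assays (plateaus 0.50 / 0 and
  0.75 / 0.50 for no/complete scrambling), curve normalization, and
  constrained double-exponential fits
  F(t) = F_s·e^(−t/τ_s) + F_f·e^(−t/τ_f) with F_s + F_f = 1.
* **Synthetic data** — a generator producing trajectories, temperature
  series, PMF-distributed samples and assay curves with known ground
  truth, so every estimator is validated end to end.

See `vignettes/scramblekit-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

Five synthetic 20 µs replicas of a 600-lipid membrane with two
scrambling sites (true rates 6.5 and 2.2 events/µs), analysed with the
default 2.1 nm detection threshold and 2 nm pathway cutoff:

```r
library(scramblekit)
spec <- synthetic_spec(
  n_per_leaflet = c(POPC = 300),
  rates = list(POPC = c(Sec61 = 6.5, TRAP = 2.2)),
  sites = list(Sec61 = c(4.5, 7.5), TRAP = c(10.5, 7.5)),
  n_frames = 2000, dt_ns = 10, seed = 42)

reps <- lapply(1:5, function(r) {
  sp <- spec; sp$seed <- 42 + r
  g  <- generate_trajectory(sp)
  st <- assign_leaflets(g$traj, g$lipids, threshold = 2.1)
  ev <- detect_events(st, g$traj, g$lipids)
  assign_events_to_sites(ev, g$sites, g$traj, cutoff = 2.0)
})
compute_rates(reps, durations_us = 20)
#>   site lipid_type rate_1_us n_replicas total_events
#>   TRAP       POPC 2.2 ± 0.1          5          216
#>   TRAP      total 2.2 ± 0.1          5          216
#>  Sec61       POPC 6.7 ± 0.3          5          670
#>  Sec61      total 6.7 ± 0.3          5          670
#>   bulk       POPC 0.0 ± 0.0          5            0
#>   bulk      total 0.0 ± 0.0          5            0
```

Both true rates are recovered within one standard error, and no event
is misattributed to the bulk. The faster site scrambles ~3× faster than
the slower one (Welch test on per-replica rates: p ≈ 1.3e-05).

Kinetics from published-scale numbers: lowering the flip-flop barrier
from 59.2 kJ/mol (protein-free) to 9.4 kJ/mol (Sec61/TRAP) at 310 K
accelerates scrambling by

```r
eyring_speedup(59.2, 9.4, 310)
#> [1] 246081140         # ~2.5e8-fold
```

and an Arrhenius fit of total scrambling rates measured at 290–330 K
(1.7, 3.3, 7.7, 14.3, 26.0 events/µs):

```r
fit_arrhenius(seq(290, 330, 10), c(1.7, 3.3, 7.7, 14.3, 26.0))
#> <arrhenius_fit> E_A = 55.12 +/- 1.47 kJ/mol, lnA = 23.37 +/- 0.57
```

An activation energy of ~55 kJ/mol is consistent with an enthalpic
barrier of ~48 kJ/mol via E_Arrh = ΔH‡ + RT ≈ 51 kJ/mol.

## Command line

A thin CLI over the same functions is installed at
`system.file("scripts/scramblekit", package = "scramblekit")`:

```sh
scramblekit eyring    --dg-ref 59.2 --dg-new 9.4 --temp 310
scramblekit arrhenius --rates rates.csv        # columns T_K,k_1us[,se]
scramblekit assay-sim --mode BSA --k-scr 0 --k-q 0.1 --t-end 600
scramblekit assay-fit --curve assay_curve.csv  # header time_s,intensity
scramblekit fep       --profile pmf.xvg --temp 310
```

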