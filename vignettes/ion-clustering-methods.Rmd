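---
title: "Quantifying ion-induced protein clustering: models and methods"
author: "ionbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ion-induced protein clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbridge)
```

## The scientific problem

Net-negative membrane proteins — SNAP25, a 206-residue SNARE protein with
43 negatively and 30 positively charged residues, is the model system —
cluster in response to divalent cations in a *biphasic* way: clustering
rises with ion concentration, peaks at intermediate millimolar levels, and
reverses at high levels. The proposed mechanism has two ingredients. At
intermediate load, one Ca²⁺ coordinates carboxylate groups of two or more
protein copies, forming salt bridges that link proteins together. At high
load, ions are abundant enough that every carboxylate pairs with its own
ion (and some with two), the protein–ion complex overcharges, and bridge
formation is suppressed — clusters disperse.

`ionbridge` implements the quantitative readouts of this phenomenon:
heterogeneity and cluster metrics for fluorescence images of membrane
sheets, ion–carboxylate coordination statistics and solvent-accessible
surface area (SASA) for molecular trajectories, formal-charge bookkeeping
for sequences, and a minimal Monte-Carlo model that exhibits the
mechanism. Because the original raw data (micrographs, trajectories) are
not distributable, seeded synthetic generators provide inputs with exact
ground truth; every analysis stage is tested against them, against
closed-form results, or against independent brute-force oracles.

## Imaging metrics

**Relative standard deviation.** The segmentation-free clustering score is
the population coefficient of variation of background-corrected pixel
intensities in a region of interest (ROI): `relative_sd()` computes
σ/μ with the population (1/n) variance. It is exactly 0 for a uniform
sheet, invariant under multiplicative intensity scaling (so lamp intensity
and exposure cancel), and *not* invariant under additive offsets — which
is why the background must be subtracted first, and why the function
refuses a non-positive corrected mean rather than returning a misleading
ratio. Per-condition values are normalized to the no-divalent-cation
control with `normalize_to_control()` as a separate, explicit step.

**Cluster counting.** `detect_clusters()` counts prominence-qualified
local maxima: a maximum is accepted when the connected region of pixels
strictly above (value − tolerance) around it contains no higher pixel.
Equal maxima connected within tolerance count once; plateau maxima report
their centroid; a constant ROI has no maxima. The tolerance (`noise_level`)
deliberately has no default — it must be chosen per dataset and held fixed
across all recordings of a comparison, because the count is monotonically
non-increasing in the tolerance and any per-image adjustment would bias
the comparison. The implementation is validated against an independent
per-candidate breadth-first-search oracle on every test fixture up to
64×64 pixels.

**Cluster radius by autocorrelation.** `autocorr_curve()` computes the
Pearson correlation between the ROI and the ROI shifted rightward by
Δ = 0, 1, 2, … pixels, on the overlapping region only (no wraparound);
curves from several ROIs of one condition are averaged pointwise with
`average_curves()`. `radius_from_autocorr()` fits a polynomial (default
order 4) and reports the shift at which the fit first crosses midway
between its value at shift 0 and a baseline taken as the fitted value at
the largest shift. The polynomial order and the baseline convention are
design choices: order 4 follows the fitted curves' gentle curvature
without chasing noise, and the largest-shift baseline is the only
reference level available without assuming a spot model. For isotropic
Gaussian objects of profile width σ the autocorrelation is
exp(−Δ²/4σ²), so the half-decay shift is 2σ√(ln 2) ≈ 1.665σ;
`autocorr_radius_to_sigma()` applies this calibration when a profile-level
size estimate is wanted. Shifts are rightward-only by default (matching
the shifted-ROI procedure the curve emulates); an isotropic four-direction
average is available but off by default.

**Punctate signal fraction.** `clustered_fraction()` segments punctate
pixels as those above mean + k·SD of the ROI (default k = 2) and reports
the share of total signal they carry. The threshold rule is the simplest
segmentation consistent with the rel. SD statistic; k is exposed because
no canonical value exists.

## The synthetic image generator

`gen_sheet_image()` emulates an immunostained membrane sheet: a constant
camera background, a diffuse signal floor, and a Poisson number of
clusters (expected count = density × field area) at uniform positions.
Clusters are isotropic 2-D Gaussians truncated at 3σ and renormalized;
`cluster_radius_nm` maps to σ one-to-one, a documented convention rather
than a claim about real microdomain profiles. The optical blur σ is folded
analytically into the cluster profile (Gaussian ⊛ Gaussian = Gaussian), so
blurring conserves signal exactly; clusters wrap at the field edge (torus)
for the same reason, making the total-signal invariant exact:
background×area + mean_signal×area, to floating-point precision.
`clustered_fraction` fixes the share of above-background signal placed in
clusters *before* noise. Noise is none, additive Gaussian (clamped at 0),
or Poisson shot noise at a configurable photon gain.

What the generator does **not** emulate: vignetting, chromatic effects,
detector correlations, membrane-sheet boundary shapes, or any biological
prior on microdomain density and size — the defaults (a few clusters per
µm², σ ≈ 60–80 nm) are chosen for testability. Passing the recovery tests
therefore shows the *estimators* are correct and well-calibrated on their
assumed forward model, not that real micrographs satisfy that model.

## Trajectory analysis

**Roles, not atom lists.** Analyses select atoms by chemical role —
carboxylate carbons (Asp CG, Glu CD, C-terminal C), backbone carbonyl
oxygens, Gln side-chain carbonyl oxygen, Ser/Thr hydroxyl oxygens,
Gln/Arg/Lys side-chain nitrogens, and the monatomic ions — assigned as a
pure function of residue name, atom name and the C-terminal flag
(`atom_role()`). Contact distances are measured ion to carboxylate
*carbon*, the same atom the RDF is defined on.

**RDF.** `compute_rdf()` histograms minimum-image pair distances and
normalizes per observer atom by shell volume and the partner group's
ideal-gas density ((N−1)/V for self-RDFs), averaging over frames and
reporting per-bin standard errors across frames. r_max is capped at half
the smallest box edge, where the minimum-image metric stops being valid.
The ideal-gas generator (`gen_ideal_gas_frames()`) calibrates the whole
chain: its g(r) must be statistically 1 everywhere.

**First-shell cutoffs.** `first_shell_threshold()` smooths g(r) with a
3-bin moving average, finds the first coordination peak, absorbs secondary
peaks whose intervening dip stays above 1 (divalent-cation coordination is
often bimodal — two binding distances to a carboxylate — and the shell
boundary is after the *second* mode), and returns the first local minimum
after the shell. A peak only qualifies above `peak_min = 1.5`, so
statistical wiggle on a featureless RDF is not mistaken for structure;
featureless RDFs fall back to a bundled default table with a warning. Only
the 0.4 nm carboxylate cutoff in that table is treated as standard; the
other roles carry plausible defaults spanning the usual 0.25–0.5 nm
first-peak range and should be overridden when an RDF is available.

**Stoichiometry.** `contact_counts()` gives per-ion and per-site contact
counts in one frame (exactly symmetric: both sides sum to the number of
contact pairs), `stoichiometry_spectrum()` tallies ions with exactly
*i* = 1…10 partners and sites with *i* = 1…3 ions over an analysis window
and divides by the frame count, and `bridging_frame_fraction()` reports
the share of frames in which every ion has at least `min_sites` contacts
(`min_sites = 1` for the all-ions-engaged sense; 2 for the strict
bridging sense — both are one call apart). Zero-contact ions and sites
are excluded from the spectra but reported separately, so either
normalization convention can be reconstructed. Windows use a
`last:<fraction>` / `last_ps:<ps>` mini-language; the default `last:0.2`
generalizes the common practice of averaging the final fifth of a run.

**SASA.** `shrake_rupley_sasa()` implements the classic point-count: each
atom's solvent-extended sphere (van der Waals + 0.14 nm probe) is sampled
with a golden-section spiral lattice (default 960 points — at that density
the isolated-sphere area is exact to ≪0.5% and two-sphere configurations
match Monte-Carlo surface integration within 2%), and a point is
accessible when outside every neighbour's extended sphere, with periodic
neighbours included. The lattice is deterministic, so SASA values
reproduce exactly; rotation invariance holds to <0.5% at 960 points. Radii
come from a bundled Bondi-style table with per-element override. Ions are
excluded as occluders by default (`include_ions = FALSE`): the protein
surface is the clustering readout, and including transiently bound ions
would mix the two signals. `window_stats()` follows the multi-copy
convention: within a run, mean ± s.e.m. across window frames; across
runs, per-run window means first, then mean ± s.e.m. with n = number of
runs.

**The bridged-frame generator.** `gen_bridged_frames()` draws, for every
ion and frame, a contact count from a user distribution, places exactly
that many sites inside the ion's contact sphere and all remaining sites
beyond threshold + margin of every ion, with ions spaced at least
2(threshold + margin) apart so contact shells cannot overlap. Contact
analysis on these frames must therefore reproduce the drawn counts
*exactly*, frame by frame — a sharp end-to-end test of the distance
machinery — while the realized spectrum fluctuates binomially around the
nominal distribution. Placement is rejection sampling with a bounded retry
budget; infeasible geometry is an error naming the frame, never a silent
degradation. Frames are statistically independent: nothing about the
generator emulates dynamics, forces, or water.

## The bridging/overcharging Monte-Carlo model

The demonstrator is deliberately minimal: `n_particles` point particles in
a periodic 2-D box (the membrane plane; 3-D is available), each carrying
`sites_per_particle` negative unit charges, plus `ion_count` divalent
ions. An ion may occupy coordination slots of sites belonging to particles
within `contact_radius_nm` (1.5 nm — generous because the particle is a
whole protein, not a single carboxylate); each site offers two slots,
mirroring the two carboxylate oxygens, and each ion binds at most
`max_sites_per_ion = 2` sites, the dominant coordination multiplicity.
The energy, in kT:

* `bind_energy_kT` (−4) per first engagement of a site and
  `second_bind_energy_kT` (−2) per second engagement — the second ion on
  an already-engaged carboxylate is the microscopic overcharging step;
* `bridge_energy_kT` (−2) per additional distinct particle an ion binds —
  the salt-bridge payoff;
* `charge_penalty_kT` (0.08) × Σ q²/√m over connected particle–ion
  complexes (q = 2·ions − sites, m = particles in the complex), plus 4 per
  unbound ion. The 1/√m factor is the Coulomb self-energy scaling of a
  compact 2-D cluster (radius ∝ √m): overcharge at fixed surface density
  then costs *superextensively*, which is what caps cluster growth. A
  plain q² penalty cannot do this — a complex sheds charge to a
  size-independent optimum and merging always halves the total penalty —
  a structural fact, not a tuning accident, and the reason the q²/√m form
  is used.

Sampling is Metropolis with particle and ion displacement moves (a move
that would stretch an existing bond beyond the contact radius is
rejected — bonds are hard constraints) and symmetric bind/unbind/replace
proposals on uniformly drawn ion–site pairs. The *replace* move (a site
swaps its resident ion for another eligible one, reverse move identical in
proposal probability and always feasible) exists because pure bind/unbind
dynamics kinetically trap the saturated regime: a bridge can only form
after a resident ion vacates, and with hundreds of free ions the vacancy
is always re-filled by the wrong ion. The number of bind proposals per
sweep is fixed at 4 × the slot count, independent of ion count, so run
time does not grow with ion load; proposal counts affect mixing speed
only, never the stationary distribution. The running energy is accumulated
from accepted increments and checked against a from-scratch recomputation
(agreement < 10⁻⁹ kT). A detailed-balance test on an exactly enumerable
two-particle/one-ion system checks the sampled state frequencies against
hand-computed Boltzmann weights.

The reference configuration (`inst/extdata/mc_reference.json`; also the
function defaults) uses 12 particles × 4 sites in a 22 × 22 nm box, 40 000
sweeps sampled every 100, and ion counts {2, 30, 120} spanning the three
regimes: too few ions to bridge; roughly the 2-per-particle load that
neutralizes while bridging; and a load high enough that slot competition
and overcharging dominate. Observables (largest and mean cluster size via
union-find over the shared-ion graph, `cluster_partition()`) are averaged
over the second half of each run across 4 seeds, echoing multi-copy
practice; a drift warning compares the third and fourth quarters. Under
this protocol the mean cluster size runs ≈1.1 / ≈11 / ≈5.5 — biphasic with
a mid-versus-high one-sided t well above the 5% critical value — while
setting `charge_penalty_kT = 0` removes the high-load decline (the
ablation's mid-to-high difference is statistically flat) and
`allow_bridging = FALSE` (ions restricted to one particle) removes
clustering entirely. Ion count is a concentration *proxy*; no quantitative
mapping to mM is claimed, and no numeric agreement with any experimental
system is asserted. An explicit screened-Coulomb energy would be the
natural next refinement.

## Sequence charge bookkeeping

`charge_profile()` applies pH 7.4 formal charges: Asp/Glu −1, Lys/Arg +1,
His neutral by default (side-chain pKa ≈ 6; `count_his_positive = TRUE` is
available, and on the bundled SNAP25B sequence the printed "30 positive"
count is reproduced only with histidine excluded — the basis for the
default). Termini (+1/−1) are optional and cancel in the net for a whole
chain. No Henderson–Hasselbalch fractional charges: these are bookkeeping
integers, not titration predictions. The ion table
(`inst/extdata/ion_properties.csv`) carries literature values — Shannon
6-coordinate effective ionic radii, Marcus hydration free energies,
Jones–Dole viscosity B coefficients, typical first-shell coordination
numbers — as versioned data with the source conventions stated in its
header.

## Numerical choices and degenerate inputs

* Minimum-image distances are validated against explicit 27-image
  enumeration to 10⁻¹²; triclinic boxes are rejected with a clear error.
* All generators draw from one private RNG per call (`with_seed()`),
  restore the caller's random state, and are byte-reproducible from their
  integer seed. The analyses themselves contain no randomness except the
  SASA lattice, which is deterministic.
* Degenerate inputs fail loudly with typed conditions
  (`ionbridge_usage_error` for bad arguments, `ionbridge_data_error` for
  bad data), e.g.: rel. SD on a non-positive corrected mean; an
  autocorrelation curve that never decays to its 50% level; a GRO frame
  missing its box line (with the line number); SASA radii missing for an
  element (naming the atoms).
* Zero-variance autocorrelation overlaps record NA and are excluded
  pointwise from curve averages.
* Problem sizes in the test-suite and acceptance script — 1000 ideal-gas
  particles × 100 frames for RDF calibration, 2000 frames for
  stoichiometry recovery, 20 seeds for image-metric recovery, 24 runs of
  40 000 sweeps for the Monte-Carlo scan — were chosen so the statistical
  tolerances (3·SE bands, 20% recovery bounds) are comfortably resolved.

## Known limitations

* The imaging arm assumes shift-invariant statistics inside the ROI and
  an isotropic, roughly Gaussian object profile when converting half-decay
  shifts to sizes; elongated or nested microdomains will bias the radius.
* The rel. SD conflates cluster density, size and occupancy changes into
  one number — by design; the complementary metrics disentangle them only
  partially.
* SASA uses a fixed radii table; force-field-specific radii change
  absolute values (relative, window-to-window comparisons are robust).
* The Monte-Carlo model has no explicit electrostatics, hydration or
  water release; it demonstrates that bridging + overcharging suffice to
  produce biphasic clustering, nothing more.
* Synthetic generators validate estimator correctness, not biological
  realism (see above).
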