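# ionbridge

Divalent cations such as Ca²⁺ drive a striking, reversible clustering of
net-negative membrane proteins: at intermediate concentrations the cations
bridge carboxylate groups (Asp/Glu side chains, the C-terminus) of
neighbouring protein copies and pull them into clusters; at high
concentrations excess ions saturate and overcharge the carboxylates, the
bridges fail to form, and the clusters re-disperse. The readouts of this
biphasic behaviour live in two very different data worlds — fluorescence
micrographs of native membrane sheets on the one hand, ion–protein
trajectories from molecular simulation on the other — and `ionbridge`
implements both analysis arms as one tested R package, together with
seeded synthetic-data generators so that every stage can be validated
against known ground truth, and a Metropolis Monte-Carlo demonstrator of
the bridging/overcharging mechanism itself.

It is intended for membrane biophysicists and structural bioinformaticians
who need reproducible, scriptable versions of these analyses rather than
interactive image-tool workflows.

## What it computes

**Imaging arm** (`sheet_imaging`): for a membrane-sheet image with pixel
size in nm,

- background-corrected mean intensity of a region of interest;
- the *relative standard deviation* (rel. SD), i.e. the coefficient of
  variation σ/μ of background-corrected pixel intensities — a
  segmentation-free clustering score that is 0 for a perfectly uniform
  sheet and grows as signal concentrates into puncta — plus normalization
  to a control condition;
- cluster counting by prominence-based local-maxima detection (a maximum
  counts only if one cannot reach a higher pixel without descending more
  than a fixed noise tolerance), giving cluster densities per µm²;
- cluster radii from pixel-shift autocorrelation: the Pearson correlation
  between the image and itself shifted by Δ pixels is fitted with a
  polynomial, and the 50% decay shift Δ½ converts to a length. For
  Gaussian objects of width σ, Δ½ = 2σ√(ln 2), and
  `autocorr_radius_to_sigma()` inverts this;
- the fraction of total signal inside punctate areas (pixels above
  mean + k·SD).

**Trajectory arm** (`traj_analysis`): for ion–protein coordinates in an
orthorhombic periodic box (GRO, XYZ or a simple CSV dialect),

- radial distribution functions g(r) between atom roles (e.g. calcium vs
  carboxylate carbons) with per-bin standard errors, and first-shell
  contact cutoffs from the first minimum after the coordination peak;
- distance-threshold contact stoichiometry: the mean number of ions
  engaging exactly *i* carboxylates per frame (and the converse,
  carboxylates engaging *i* ions), at the standard 0.4 nm cutoff;
- the fraction of frames in which *every* ion is salt-bridge engaged;
- Shrake–Rupley solvent-accessible surface area (0.14 nm probe,
  deterministic golden-spiral point lattice, periodic occluders) with
  windowed means ± s.e.m. across frames or across multi-copy runs — SASA
  falls as peptides oligomerize, so it doubles as a clustering readout.

**Mechanism demonstrator** (`bridge_mc`): a 2-D Metropolis model of
particles carrying negative binding sites and diffusing divalent ions.
Bridging (one ion bound to sites of two particles) is rewarded; each
connected particle–ion complex pays a Coulomb-self-energy-like charge
penalty `q²/√m`. Across low/intermediate/high ion counts the model
reproduces the biphasic cluster-size curve, and ablations isolate the
ingredients: removing the charge penalty removes the high-concentration
decline; forbidding cross-particle binding removes clustering entirely.

**Sequence bookkeeping** (`protein_charge`): formal side-chain charges at
pH 7.4 (Asp/Glu −1, Lys/Arg +1, His neutral by default), subsequence
extraction, and ion property ratios (charge/crystal radius, hydration
energy per coordinated water) from a bundled literature table. The
206-residue rat SNAP25B sequence ships with the package as the model
anionic membrane protein: 43 negative vs 30 positive residues, and its
SN1-motif peptide Leu35–Met64 carries a net side-chain charge of −6.

## Worked example

Generate a synthetic membrane sheet with known ground truth and quantify
it:

```r
library(ionbridge)

g <- gen_sheet_image(image_spec(
  width_px = 128, height_px = 128, pixel_size_nm = 40,
  cluster_density_per_um2 = 2, cluster_radius_nm = 80,
  clustered_fraction = 0.6, mean_signal = 50, background_level = 10,
  noise_model = "poisson", seed = 42))
g$n_clusters
#> [1] 62

r <- roi(0, 0, 128, 128)
relative_sd(g$image, r, background = 10)
#> [1] 1.31
detect_clusters(g$image, r, noise_level = 20)$count
#> [1] 68
rad <- radius_from_autocorr(autocorr_curve(g$image, r, max_shift_px = 12))
c(half_decay_nm = as.numeric(rad), sigma_nm = autocorr_radius_to_sigma(rad))
#> half_decay_nm      sigma_nm
#>         124.0          74.5
```

The image was built with 62 clusters of profile sigma 80 nm; prominence
counting finds 68 maxima (shot noise adds a few), and the autocorrelation
half-decay of 124 nm converts back to an estimated spot sigma of 74.5 nm.

The trajectory arm, on a generated fixture whose every ion engages one or
three carboxylates with equal probability:

```r
b <- gen_bridged_frames(bridged_frame_spec(
  n_ions = 3, n_sites = 30, contact_distribution = c("1" = 0.5, "3" = 0.5),
  n_frames = 500, seed = 7))
stoichiometry_spectrum(b$trajectory, window = "all")
#> <stoichiometry_spectrum> over 500 frames (window all ) at 0.4 nm
#>   ion with i sites:  i=1: 1.48, i=3: 1.52
#>   site with i ions:  i=1: 6.04
```

The nominal spectrum is {i=1: 1.5, i=3: 1.5} ions per frame; the measured
1.48/1.52 recovers it. And the sequence arithmetic:

```r
charge_profile(subsequence(snap25b_sequence(), 35, 64))
#> <charge_profile> 30 aa at pH 7.4: 9 negative, 3 positive, net -6
```

End-to-end runs over whole image sets or trajectories, with CSV/JSON
outputs and provenance records, are `run_image_pipeline()` and
`run_traj_pipeline()`.

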