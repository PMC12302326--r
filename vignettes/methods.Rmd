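---
title: "Methods: docking, trajectory analytics and variant evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: docking, trajectory analytics and variant evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padock)
```

padock supports directed-evolution campaigns on polyamide-degrading
hydrolases (nylonases). It covers the desk-scale computations of such a
campaign: building flexible 6-aminohexanoic-acid (6-AHA) oligomer
substrates and docking them into an enzyme pocket, analysing molecular
dynamics trajectories for enzyme–substrate interactions, evaluating variant
libraries kinetically and thermodynamically, and profiling family
conservation. This vignette documents the models, their assumptions, and
the main parameters.

## Substrate model

A PA 6 (nylon 6) chain fragment is modelled as `n` 6-AHA repeat units with
explicit hydrogens and two chemistry-consistent terminations: an acetyl cap
with a carboxylate terminus (`Ace`/`COO-`, formal charge −1) or an
N-methylamide cap with an ammonium terminus (`NMe`/`NH3+`, +1). Geometry is
generated by natural-extension reference-frame (NeRF) placement from
internal coordinates; amide (omega) dihedrals are frozen at 180° (trans),
all single bonds between heavy atoms of degree ≥ 2 are rotatable.
`enumerate_orientations()` yields the two chain orientations relative to
the pocket, which are docked independently.

```{r}
spec <- oligomer_spec(4, "Ace", "COO-", 1)
oligomer_label(spec)
olig <- build_oligomer(spec)
nrow(olig$structure$atoms)   # 83 atoms for the tetramer
nrow(olig$rotatable)
```

The mid-chain amide closest to the chain centre is tagged as the scissile
(attack) amide for site-proximity analyses.

## Incremental fragment-growth docking

The receptor is rigid and fully parameterised (partial charges and
Lennard-Jones sigma/epsilon per atom). The score is the short-range
interaction energy

E = Σ 4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶] + k_e q_i q_j / r,  r ≤ cutoff,

with Lorentz–Berthelot combination and k_e = 1389.35458 kJ mol⁻¹ Å e⁻².
Docking proceeds in three stages:

1. **Seeding** (`seed_placement()`): the first repeat unit plus its cap is
   placed with uniform random positions inside a sphere (default 8 Å)
   around the catalytic-site centroid and uniform random orientations
   (quaternion method). Placements with any heavy atom closer than 2.0 Å
   to a receptor heavy atom are rejected; survivors are scored and the best
   `keep_k` retained. If every sample clashes, an error suggests enlarging
   the seeding radius.
2. **Extension** (`extend_increment()`): the next unit is grown by
   full-factorial enumeration of its rotatable-bond dihedrals over
   candidates {180°, 60°, −60°} plus uniform jitter. Candidate sets are
   deterministic and trans-first: with fewer than three samples per bond
   the extended (trans) conformer is always retained. Conformers with
   internal clashes (heavy-atom pairs ≥ 3 bonds apart closer than the
   threshold) or receptor clashes are discarded; the global best `keep_k`
   across all parents continue.
3. **Clustering** (`cluster_and_rank()`): completed poses are
   leader-clustered in score order on heavy-atom coordinate RMSD without
   superposition (poses share one receptor frame). Clusters are ranked by
   population, then mean score.

Two summary energies are reported deliberately: `binding_energy_estimate`
is the best score inside the top-ranked (most populated) cluster — the
reported affinity proxy, favouring reproducible basins over single deep
poses — while `best_score` is the global minimum over all final poses,
which is the quantity comparable against exhaustive enumeration. They can
differ when a broad shallow basin out-populates the basin holding the
global minimum.

Determinism: each orientation draws from its own substream
(`seed + (orientation − 1) × 10007`), so a one-orientation run is exactly
reproducible inside a two-orientation run, and fixed seeds give
bit-identical results.

```{r}
cx <- make_toy_complex("channel", seed = 1)
res <- dock_oligomer(cx$structure, oligomer_spec(2, "Ace", "COO-", 1),
                     cx$table, dock_config(n_samples = 200, keep_k = 10,
                                           n_dihedral_samples = 2), seed = 1)
glance(res)
```

## Trajectory analytics

Trajectories are per-replica lists of coordinate frames over a fixed
topology with named atom groups (`enzyme`, `substrate`, donor/acceptor
selections, pocket-axis markers).

- **Contacts** (`contact_frequencies()`): a residue is in contact in a
  frame when any of its atoms is within the cutoff (default 2.5 Å,
  inclusive) of any substrate atom; frequencies are percentages of frames.
  Replicas are combined as mean ± SEM (`aggregate_contacts()`), and
  `select_hotspots()` applies the ≥ 50 % rule with explicit exclusions
  (e.g. catalytic residues that must not be mutated).
- **Hydrogen bonds** (`detect_interactions(kind = "hbond")`): donor–acceptor
  distance ≤ 3.5 Å and donor–H–acceptor angle ≥ 150°, requiring explicit
  hydrogens. **Salt bridges**: charged-atom distance ≤ 4.0 Å with partial
  charges beyond ± 0.25 e. Occupancy is the percentage of frames.
- **Conditional energies** (`conditional_energy()`): the enzyme–substrate
  interaction-energy series is averaged separately over bonded and
  unbonded frames; ΔE = E_bound − E_unbound with spread combined in
  quadrature. States with fewer than `min_frames` frames mark the delta
  undefined rather than reporting a noisy number. The two conditional
  means always reconstruct the grand mean exactly (a tested invariant).
- **Side-chain states** (`classify_sidechain()`): an aromatic ring is
  classified by the angle between the CB→ring-centroid vector and the
  pocket axis (boundary 45°), giving per-frame states and fractions.

## Kinetics and stability

- `calibrate_and_quantify()` maps photometric readings onto a linear
  amine calibration with range flags; `background_correct()` subtracts
  non-enzymatic release.
- `specific_activity()` returns µmol released amine per hour per mg
  enzyme; volume cancels, and molar vs mass enzyme concentrations are
  cross-checked within 2 %.
- `fold_change()` propagates SEMs first-order on ratios and applies the
  one-decimal half-up reporting convention.
- `fit_mm()` fits v = Vmax·x/(Km + x) by Levenberg–Marquardt with
  restarts, for conventional (substrate-titrated) and inverse
  (enzyme-titrated, excess solid substrate) Michaelis–Menten designs.
- `degree_of_depolymerization()` reports percent w/w of the loading
  released as soluble products on a repeat-unit mass basis (113.16 g/mol),
  with the free-monomer basis (hydrolysis adds water back) as an option,
  plus the monomer share of released repeat units.
- `extract_tm()` locates the melting temperature at the smoothed-derivative
  maximum and refines it with a two-state Boltzmann fit; transitions at the
  grid boundary raise an error instead of extrapolating.
- `classify_epistasis()` uses the multiplicative null on fold-changes
  (additive in log space): a combo below expected − kσ is negative
  epistasis.

```{r}
classify_epistasis(tibble::tibble(fold = c(2.8, 3.0), sem = c(0.15, 0.15)),
                   c(5.3, 0.3))
```

## Conservation

`column_profile()` computes per-column information content
IC = log₂ 20 − H over gap-renormalised amino-acid frequencies (gaps are
reported separately, no small-sample correction by default).
`variable_in_conserved()` nominates low-IC positions whose surrounding
window (self excluded) is highly conserved — candidate specificity
positions inside conserved patches.

## Synthetic generators and their scope

All statistical claims are tested against generators with *planted truth*
(`planted_truth()`, `make_trajectory()`, `make_screen_plate()`,
`make_melt_curve()`, `make_msa()`, `make_mm_data()`, `make_timecourse()`).
They plant target statistics directly at the frame/record level (Bernoulli
contact toggles, Coulomb-algebra energy levels, lognormal activity noise)
rather than simulating physics: the surface under test is the analysis
code, not an MD engine. Planted targets that are jointly impossible (a
donor in contact less often than it is hydrogen-bonded) are rejected at
construction.

## Problem sizes and limitations

Designed scales: oligomers of 1–4 units (≤ ~150 atoms), receptors of
10²–10⁴ atoms, hundreds of seed samples, trajectories of 10²–10³ frames
and ≤ 10 replicas, alignments of ≤ 10³ columns. Everything is plain R;
docking a 2-unit oligomer with default settings takes seconds, a full
`run_pipeline()` under a minute.

Limitations: the receptor is rigid, solvent is implicit in the
short-range score (no electrostatic screening model), the clash filter
exempts hydrogens, pose clustering assumes a common receptor frame, and
the score is a ranking proxy, not a calibrated free energy.
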