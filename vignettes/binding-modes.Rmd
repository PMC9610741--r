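---
title: "Membrane binding modes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane binding modes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memmodes)
```

# The picture

A peripheral membrane enzyme such as a secreted phospholipase A2 binds a
zwitterionic bilayer not in one orientation but in a few discrete *modes*.
Each mode is operationally defined by three observables this package
computes:

* a **contact set** — the residues that touch lipids in a stable fashion;
* an **altitude** — the height of the protein's top surface over the
  membrane interface, defined as the mean phosphorus position of the lipid
  head groups (this definition makes simulation altitudes directly
  comparable with AFM heights over a supported bilayer);
* a **population**, and therefore a Boltzmann energy
  $\Delta E_{ij} = -k_B T \ln(p_j/p_i)$.

The package implements the full chain from raw inputs (structures,
trajectories, height images) to the mode-level summary (assignment, energy
diagram, admissible switching path), plus seedable synthetic-data
generators that plant every one of those quantities so the chain can be
validated by parameter recovery.

# Contact analysis

A contact is a protein–lipid particle pair with centre–centre distance
*strictly below* the cutoff, 0.6 nm by default — the conventional
bead-contact distance at coarse-grained resolution. Distances are plain
Euclidean by default; minimum-image distances are available behind a flag
(`contact_config(periodic = TRUE)`) because desk-scale synthetic patches
are finite, while real simulation boxes wrap. Solvent particles are never
contact partners.

Per-residue statistics count a residue once per frame no matter how many of
its particles touch. A residue is a *stable* contact residue when its
contact fraction over the analysis window reaches `stable_fraction`,
default 0.5. The value is a genuine free choice: any threshold between
the planted ≥ 0.9 contact fraction of bound residues and the ≤ 0.05 of
unbound ones recovers the same sets on clean data, and 0.5 sits at the
natural midpoint; it is echoed in every report so downstream readers can
audit it.

Landing is detected as the first frame opening a run of at least
`persistence` (default 5) consecutive frames with a positive contact
count. Fingerprints and altitude distributions use only the post-landing
window, because the approach segment would dilute both.

# Mode classification

A trajectory's fingerprint is its per-residue contact-fraction vector.
Fingerprints are compared by Jaccard similarity of their stable supports
(the classification is at heart about *which* residues bind, not how
often), with cosine similarity on the raw vectors as an alternative.
Single-linkage agglomeration merges any pair at similarity ≥ 0.5; at
threshold 0 everything merges, above 1 nothing does. Mode labels are
assigned by descending mean contact intensity (bead contacts per frame), so
mode 1 is always the high-intensity, deeply bound orientation; ties break
toward lower mean altitude.

Mode *regions* are compared on the structure: sets sharing a residue are
"overlapping"; otherwise any cross-pair within 0.8 nm (about two bead
diameters) makes them "neighboring"; otherwise "disjoint". Disjoint
regions cannot exchange the protein directly — the transition-path search
(Dijkstra over uphill energy costs, with an infinitesimal per-edge penalty
so equal-cost ties resolve to fewer hops) only traverses connected pairs.

Per-residue mobility is summarised as RMSF after least-squares rigid
superposition of each frame onto the mean conformation (two superposition
passes; the rotation solver is the same Kabsch routine the backmapper
uses). For isotropic per-coordinate jitter of sd $\sigma$ the expected
RMSF is $\sigma\sqrt{3}$ (up to the six fitted degrees of freedom), which
the tests verify.

# Altitude

The interface is the mean z of phosphorus-labelled lipid particles; by
default only the upper leaflet (above the midpoint of the min and max
phosphorus z) is averaged, since the protein binds one face. Two protein
reference points are computed: `"top"` (maximum protruding particle — the
default, because the AFM observable is a top-surface height) and `"com"`
(centre of geometry). Which point a given simulation study used is often
ambiguous; both are reported rather than resolved. Altitudes may be
negative if the reference point dips below the phosphorus plane.

# AFM analysis

The bilayer background of a height field is the mode of the height
histogram (densest 0.05 nm bin, refined by the median of pixels within two
bins), robust to sparse particle coverage. Detection thresholds at 0.5 nm
above background and keeps local maxima at least 4 nm apart (taller peak
wins), roughly one globule diameter after tip convolution. The
per-particle statistic is the *peak* altitude, matching the top-surface
altitude convention.

The pooled altitudes are deconvolved by a K-component 1-D Gaussian mixture
fitted with EM: initial means are sample quantiles (perturbed across
restarts), convergence is a log-likelihood gain below 1e-8, restarts that
collapse a component (sd below 1e-6 nm) are discarded, and the
log-likelihood trace of the winning restart is exposed — it must be
non-decreasing, and the tests assert that on every fit. EM on raw samples
avoids the bin-width sensitivity of the classical binned fit; that
classical sum-of-Gaussians least-squares fit is nevertheless included
(`fit_gaussian_histogram`, Freedman–Diaconis bins by default after
observing that very fine bins can trap the optimiser in noise spikes) and
agrees with EM on planted fixtures. K is a user choice — three, for this
system, by inspection of the histogram; a BIC sweep helper exists but is
never applied automatically.

# Energetics

$k_B = 0.0083144626$ kJ/(mol·K); energies are reported in kJ/mol and kT.
The temperature default is 295 K, the simulation bath temperature of the
study this mirrors (ambient 298 K would change energies by 1%;
configurable). The most populated mode sits at zero. Path costs count
only uphill steps, because mode-switching feasibility is about barriers
paid, not equilibrium sums.

With the default populations (0.430, 0.346, 0.224) the 2→3 step costs
twice the 1→2 step. That is by construction: the deepest population is
0.43, and the remaining two weights are the unique solution of
$w_2 + w_3 = 0.57$ with $\ln(w_2/w_3) = 2\ln(w_1/w_2)$, the documented
two-fold energy relation. The tests verify the ratio analytically.

# Backmapping

`kabsch_fit` is the standard SVD Kabsch solver with the smallest singular
vector sign-corrected, so mirror inputs still yield a proper rotation
(det +1 within 1e-9); collinear point sets are rejected.
`backmap_protein` pairs C-alpha atoms to backbone beads by residue index
(never spatially) and applies one rigid transform to the whole reference —
justified when the internal structure barely changes during the
coarse-grained run, which the reported residual rmsd lets the user check.
No side-chain rebuilding is attempted.

# What the generators emulate — and what they do not

`make_toy_protein` places one bead per residue on a jittered Fibonacci
sphere (~3 nm diameter at 134 residues, the real enzyme's size), with a
guaranteed 0.3 nm minimum separation. At the default size the mode-1 and
mode-3 contact patches are planted on opposite caps so the two regions are
geometrically disjoint while mode 2 bridges them through shared residues —
the surface topology the adjacency analysis probes. The default mode
specifications use contact sets of 17, 10 and 6 residues (the canonical
interfacial surface; the Trp128 face; the 105–115 β-loop) with overlaps
only between consecutive modes, and altitudes 1.74, 2.37 and 2.90 nm.

`make_bilayer_patch` builds two flat leaflets (15 × 15 lipids each by
default, 0.8 nm lattice spacing, phosphorus plane at ±2.0 nm) with static
bead jitter. `simulate_binding_trajectory` constructs a bound pose —
contact residues pinned 0.05 nm above the phosphorus plane (inside the
0.6 nm cutoff of the head-bead lattice for any lateral offset), all other
residues lifted ≥ 0.8 nm (outside any possible contact), one apex residue
at the planted altitude — then adds a rigid vertical displacement
~N(0, altitude_sd) per frame plus i.i.d. per-residue jitter. The apex
carries no z-jitter, so the top-surface altitude follows exactly the
planted Gaussian law (jitter on the topmost of many residues would bias
the maximum upward). The first 10% of frames descend from 1.2 nm above
with a 0.7 nm clearance floor, so the landing frame is planted exactly at
the end of that segment; "rapid landing" is all the segment represents.

AFM fields are a zero background plus isotropic Gaussian caps of lateral
sd 1.5 nm (a few-nm tip-convolved globule; no real tip model), peak
heights drawn from the altitude mixture, i.i.d. pixel noise, and
rejection-sampled centres at ≥ 6 nm separation. Population widths are
0.15 nm by default — a value chosen as plausible for AFM height scatter,
not measured; it is deliberately well below the 0.53–0.63 nm separation of
the population means, so the three populations are resolvable.

None of this is membrane physics: there are no forces, no lipid dynamics
(lipids are static), no membrane undulations, no tip artefacts, no drift.
Passing recovery tests therefore demonstrates that the *estimators* are
correct and internally consistent — not that they would be unbiased on
real data, where interface roughness, tip convolution and conformational
change all enter.

# Numerical choices and degenerate inputs

* Units: nm everywhere internally; PDB and XYZ files are Å on disk and
  converted on read/write. Frames, particles and residues are indexed
  1-based, the R convention.
* The contact cutoff is a strict inequality; a pair at exactly 0.600 nm is
  not a contact. The contact search must (and does, property-tested)
  match an all-pairs brute-force oracle exactly.
* Zero-vector fingerprints have cosine similarity 0 by definition, with a
  warning.
* Populations that do not sum to 1 within 1e-6 are renormalised with a
  warning; zero or negative populations are domain errors.
* Mixture components are always reported with ascending means regardless
  of initialisation; weights renormalise to 1 within 1e-9.
* Empty files, ragged height-field rows, frame/topology size mismatches
  and collinear Kabsch inputs raise errors naming the offending line,
  frame or condition.

# Problem sizes

The shipped study uses six 200-frame trajectories over a 15 × 15-lipid
patch for mode classification, 556-frame runs (500 post-landing frames)
for altitude recovery, 2000 mixture samples / 600 detected particles for
the AFM branch, and 50–100 seeded replicates for the property suites —
sizes at which the recovery tolerances (3·sd/√n for means, ±4 points for
weights) are comfortably binding and the whole analysis runs in well under
a minute on one core.

# Known limitations

* Mode classification assumes contact fingerprints are stationary after
  landing; a trajectory that genuinely switches modes mid-run would get a
  blended fingerprint (detecting switches is future work).
* The interface is a single global plane; local deformation under the
  protein footprint is ignored.
* Histogram and EM fits can disagree when components are closer than
  about two sds; the package reports both rather than arbitrating.
* Backmapping is rigid; it cannot repair genuine conformational change.
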