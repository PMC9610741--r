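# memmodes

Analysis toolkit for characterising how a peripheral membrane protein sits
on a lipid bilayer, built around the observation that a secreted
phospholipase A2-type enzyme does not bind a membrane in a single pose but
switches between a small number of discrete **binding modes** — each a stable
orientation defined by (i) a reproducible set of residues in lipid contact,
(ii) a characteristic altitude of the protein top over the membrane
surface, and (iii) a relative population, hence a Boltzmann energy.

The package is aimed at people analysing coarse-grained / atomistic
membrane-binding simulations together with AFM imaging of proteins on
supported bilayers, and at anyone who wants a fully synthetic, planted-truth
test bed for such analyses.

## What it computes

**Contact maps and landing.** A contact is a protein–lipid particle pair at
centre–centre distance strictly below 0.6 nm. For a trajectory the package
reports contacts per frame, the fraction of frames each residue spends in
contact, the *stable* contact residues (fraction ≥ 0.5 by default), and the
landing frame (first persistent contact run).

**Mode classification.** Each trajectory is reduced to a contact
fingerprint (per-residue contact fractions over the post-landing window);
fingerprints are merged by single-linkage clustering on Jaccard similarity
of their stable supports. Modes are numbered by descending contact
intensity, so mode 1 is the orientation with the most contacts (the
canonical interfacial binding surface), and mode regions are classified
pairwise as overlapping / neighboring / disjoint on the structure.

**Altitude.** The membrane interface (altitude 0) is the mean position of
the phosphorus atoms of the lipid head groups; the protein altitude is the
distance from that plane to the top surface of the protein (or its centre
of geometry), the same observable an AFM height image gives.

**AFM population deconvolution.** Particles detected on height fields
yield peak altitudes *Z*; their distribution is decomposed into a sum of
*K* Gaussians,

    p(Z) = sum_k  w_k * N(Z | mu_k, sigma_k^2),

fitted by maximum-likelihood EM with restarts (a binned least-squares
sum-of-Gaussians backend is included as a cross-check).

**Boltzmann energetics.** With mode populations p_i known, energy
differences follow

    dE_ij = -kB * T * ln(p_j / p_i),          T = 295 K by default,

and allowed mode-switching paths are those that traverse only overlapping
or neighboring mode regions, minimising the summed uphill energy.

**Backmapping.** A coarse-grained pose is converted to an atomistic one by
least-squares rigid superposition (Kabsch) of the reference C-alpha atoms
onto the backbone beads.

**Synthetic data.** Seedable generators produce bilayer patches with an
identifiable phosphorus plane, a 134-residue toy protein with planted
contact patches, bound-state trajectories with planted contact sets /
altitudes / jitter, and AFM height fields with particle altitudes drawn
from a planted three-population mixture — so every estimator in the package
can be validated by parameter recovery.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data with planted ground truth:

```sh
Rscript analysis/01_simulate.R        # six trajectories + AFM field batch
Rscript analysis/02_contacts_modes.R  # contact maps -> mode clustering
Rscript analysis/03_altitude.R        # altitude distributions per mode
Rscript analysis/04_afm.R             # AFM particle detection + mixture fit
Rscript analysis/05_energetics.R      # Boltzmann diagram + transition path
Rscript analysis/06_backmap.R         # CG -> atomistic rigid backmapping
```

Six runs are planted with the start→mode mapping {1}→mode 1,
{2,4,5,6}→mode 2, {3}→mode 3. The contact/clustering driver prints:

```
six starts reduced to 3 modes; partition {1} {2,4,5,6} {3}
mode 1: 17 stable residues, mean 28.4 contacts/frame
mode 2: 10 stable residues, mean 17.8 contacts/frame
mode 3: 6 stable residues, mean 10.6 contacts/frame
region adjacency (1,2): overlapping  (2,3): overlapping  (1,3): disjoint
```

i.e. the six starting orientations collapse onto three modes, mode 1 has
the highest contact intensity, and the mode-1/mode-3 surface regions share
no surface — a switch between them must pass through mode 2. The altitude
driver recovers the planted mode altitudes:

```
mode 1: top altitude 1.738 nm (planted 1.74)
mode 2: top altitude 2.372 nm (planted 2.37)
mode 3: top altitude 2.906 nm (planted 2.90)
```

and the AFM branch recovers the planted populations from 600 detected
particles across 8 fields:

```
population 1: 1.733 +/- 0.151 nm, weight 41.8% (planted 1.74 nm, 43.0%)
population 2: 2.326 +/- 0.145 nm, weight 32.0% (planted 2.37 nm, 34.6%)
population 3: 2.862 +/- 0.168 nm, weight 26.2% (planted 2.90 nm, 22.4%)
```

The energetics driver turns the fitted weights into the energy diagram
(mode 1 at 0, here 0.655 and 1.146 kJ/mol for modes 2 and 3) and reports
the admissible switching path `1 -> 2 -> 3`.

All tables land under `results/`.

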