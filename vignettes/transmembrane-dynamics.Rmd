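---
title: "Conformational dynamics of transmembrane helix bundles: methods and design"
author: "HelixDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational dynamics of transmembrane helix bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HelixDynamics)
```

# Scope

HelixDynamics analyses molecular-dynamics ensembles of membrane-embedded
helix-bundle proteins — the seven-transmembrane (TM1–TM7, plus the
amphipathic helix 8) architecture of class-A G-protein-coupled receptors is
the motivating case. Given a topology (atom names, author-style residue
numbering, segment assignments) and a coordinate trajectory, it computes:

* least-squares superposition and RMSD/RMSF fluctuation statistics with
  replica aggregation;
* dictionary-based secondary-structure accounting from backbone
  hydrogen-bond patterns;
* residue contact maps and geometric hydrogen-bond occupancies;
* membrane number-density profiles, hydration by integration over the
  hydrophobic core, and bilayer-topology detection;
* essential dynamics: positional covariance, PCA, projections, the
  cosine-content convergence diagnostic, principal-motion displacement
  fields, and regression planes with categorical (dummy) group offsets;
* dynamical cross-correlation matrices (DCCM) and correlation-network
  community analysis by the Girvan–Newman algorithm, with a modularity
  trace and inter-segment connectivity verdicts.

A synthetic-ensemble generator with *planted* statistical structure is a
first-class part of the package: it supplies ground truth against which
every stage is validated, because production MD trajectories are rarely
redistributable.

# Superposition and fluctuations

`superpose()` solves the orthogonal Procrustes problem by SVD (Kabsch),
mass-unweighted, returning a proper rotation (det = +1), translation, and
the minimized RMSD. All time-resolved statistics use **frame 1 as the
reference conformation** — the conformation at time zero — rather than an
iterated mean structure; this is the simplest reproducible convention and
the one most trajectory studies report. `rmsdSeries()` lets the fit
selection differ from the measure selection (e.g. fit on the whole TM
domain, measure one helix). `rmsfProfile()` computes per-atom
root-mean-square displacement about the time-mean position after each
replica is fitted to its own first frame; replica statistics are the
unweighted mean ± SD across replicas, one value per atom per replica, with
unequal replica lengths allowed.

Two conventions worth stating explicitly:

* **Atom indices are 1-based** throughout the R API (selections return
  1-based indices into the topology's atom table); residue numbers are the
  author-provided biological numbering (e.g. 358–646 for a receptor TM
  domain).
* Fitting removes six rigid-body degrees of freedom from the 3N
  fluctuation space. For large selections the effect on RMSF is
  negligible (order 6/3N in variance), but for analyses that must recover
  *planted* inter-segment correlations it matters — see the DCCM section.

# Secondary structure

`assignSecondaryStructure()` re-implements the hydrogen-bond dictionary
approach: a backbone H-bond is declared when the Kabsch–Sander
electrostatic energy

$$E = 0.084 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \cdot 332\ \text{kcal/mol}$$

falls below −0.5 kcal/mol. Amide hydrogens are rebuilt at 1.0 Å from N
along the bisector of the N→C(prev) and N→CA directions, so explicit
hydrogens are not required. α-helix (H) is assigned from two consecutive
i→i+4 turns (marking residues i+1…i+4); 3-10 (G) and π (I) helices follow
the same pattern with i→i+3 and i→i+5; isolated turns are T and everything
else C. Strand (E) and bend (S) are part of the class vocabulary but are
**never assigned**: β-ladder bookkeeping is deliberately out of scope for a
helix-bundle package, and a TM bundle contains no strands. Per-segment
helix residue counts are reported per frame and summarized as replica
mean ± SD.

On an ideal 20-residue helix built by the generator the assignment is
C + 18×H + C: the 4-turn holds for donors 1–16 and consecutive turns mark
residues 2–19, so "20 minus end effects" is exactly 18.

# Contacts and hydrogen bonds

`contactMap()` declares a residue contact when the minimum heavy-atom
distance between the focal atoms and the partner residue is at most
4.5 Å (a flag; no universal convention exists) and reports per-frame events
plus occupancies. `hbonds()` uses the common geometric gate —
donor–acceptor heavy distance ≤ 3.5 Å and donor–H–acceptor angle ≥ 120° —
and tracks each (donor, H, acceptor) triplet separately, so chemically
equivalent acceptors (the two carboxylate oxygens of an aspartate)
accumulate independent occupancies.

# Density profiles, hydration, bilayer topology

`densityProfile()` histograms atom groups along the bilayer normal z with
the origin at the bilayer midplane. The midplane is located per frame from
the phosphate-like group by a mean-split of the z values refined once
(a plain median split can land inside one leaflet when leaflet occupancies
are unequal — a real failure mode we hit with randomly assigned slabs).
Densities are normalized by the bin volume dz × A, with A the
*time-averaged* lateral box area, so the integral of each group's density
exactly equals its frame-averaged atom count; this conservation is a
validity condition of the `DensityProfile` class, not merely a test.

`hydrationCount()` integrates the water density over a z-interval —
(−10, 10) Å by default, the operational definition of the interhelical
water count over the hydrophobic core. A lateral mask (distance to the
bundle axis) is deliberately *not* applied by default: the core-interval
integral is the documented operational definition, and a mask would change
the measurand silently.

`detectBilayerTopology()` defines the hydrophobic core as the smallest
symmetric interval holding the central 90% of the methyl-like density and
each water–lipid interface as the interval within half-maximum of the
corresponding phosphate leaflet peak; a phosphate distribution without two
leaflets across the midplane is an error. On generated boxes with methyl
in |z| < 10 Å and phosphates in 15 < |z| < 25 Å both are recovered within
one bin width. Profiles intended for topology detection should average
tens of frames (we use 40 in validation): the half-maximum rule on a
single frame of a few hundred pseudo-atoms is shot-noise limited, exactly
as in real density profiles.

# Essential dynamics

`covarianceModel()` accumulates the mass-unweighted 3N × 3N positional
covariance of the Cα selection over frames resampled at a 4 ps stride
(default; 0 keeps every frame), after superposition onto frame 1, and
eigen-decomposes it. Class validity enforces symmetry, the eigenvalue
floor (≥ −10⁻¹⁰), the trace identity Σλ = tr C, and eigenvector
orthonormality.

`projectTrajectory()` computes p_i(t) = v_i · (x(t) − ⟨x⟩).
`cosineContent()` implements the single half-period diagnostic

$$CC = \frac{2}{T} \frac{\left( \int_0^T \cos(\pi t / T)\, p(t)\, dt
\right)^2}{\int_0^T p(t)^2\, dt}$$

with trapezoid integrals over the actual frame times. CC is invariant to
scaling p and to affine rescaling of the time axis; CC of cos(πt/T) is 1
and of any constant is 0. Values near 1 flag random-diffusion-like
(unconverged) sampling. On drift-only synthetic ensembles (pure random
walks of the atomic means) the median PC1 cosine content across 50 seeds
is ≈ 0.99, squarely in the diffusive regime.

`motionField()` spans the PC motion between the 1st and 99th percentiles
of the projection rather than min/max — robust to single-frame outliers —
and emits the two extreme conformations alongside the per-atom vectors;
swapping the percentiles negates the field exactly.

`fitMotionPlanes()` is ordinary least squares of a designated scalar
response on lateral position with dummy-coded group offsets
(phenotype/replica). Offsets are tested against the baseline with
two-sided t-tests, Holm-corrected, at α = 0.05 (a stated choice — no
universal procedure exists for "significant offset"). Rank-deficient
designs are an error naming the collinear columns, never a silent drop.

# Correlation networks

`dccm()` computes c_ij = ⟨Δr_i · Δr_j⟩ / √(⟨Δr_i²⟩⟨Δr_j²⟩) from 3D
displacements about each atom's time mean, frames resampled at a 100 ps
stride and superposed onto frame 1. The diagonal is exactly 1 and a
zero-variance atom is an error naming the atom.

`buildNetwork()` connects residue pairs with |c_ij| ≥ 0.7 (default) and
sequence separation ≥ 2. Three deliberate choices:

* **Absolute value**: anti-correlated pairs also communicate; sign is kept
  only in the DCCM itself.
* **Correlation-only edges** by default. The classic protein-network
  recipe additionally intersects with a physical contact map; that variant
  is available by intersecting with `contactMap()` output, but the default
  reproduces pure correlation thresholding, with `minSeqSeparation = 2`
  suppressing trivial backbone-neighbour edges.
* **Unweighted shortest paths** for betweenness; |c_ij| is retained as an
  edge attribute for reporting only.

`girvanNewman()` (compiled kernel; Brandes accumulation for edge
betweenness) iteratively removes the highest-betweenness edge — ties broken
deterministically by lexicographic edge order, so traces are exactly
reproducible — and records the Newman–Girvan modularity
Q = Σ_k (e_kk − a_k²) of the component partition, evaluated on the
*original* edge set, after every removal. The returned partition maximizes
Q along the trace (earliest step on ties); an edgeless graph yields
singleton communities with Q defined as 0. Optimal Q values for
MD correlation networks typically land in 0.4–0.7; the package reports Q
but never asserts that band.

`filterCommunities()` is a reporting view (communities of ≥ 10 Cα atoms by
default); the partition itself never changes. `connectivityReport()`
declares two segments connected when an edge of the network links a
reported community *dominated* (plurality, ties allowed) by one segment to
a community dominated by the other, or when a single reported community is
jointly dominated by both; the supporting residue pairs are returned with
the verdict.

**Fit-reference effect.** Superposing on the full Cα set partially absorbs
a correlated block's common-mode motion: with a ρ = 0.9 block spanning
2 of 7 helices, whole-set fitting depresses the recovered cross-correlation
to ≈ 0.81. Fitting on the *uncorrelated core* (the standard "fit on the
stable core" practice, via `dccm(fitSelection = ...)`) recovers ≈ 0.86–0.89.
The network stage is insensitive to this because the 0.7 cutoff sits well
below either value; amplitude-accurate correlation estimates should fit on
a reference frame not involved in the motion of interest.

# The synthetic-ensemble generator

`makeBundleReference()` builds ideal α-helices from standard internal
coordinates (φ = −57°, ψ = −47°, ω = 180°; N–CA 1.458, CA–C 1.525,
C–N 1.329, C=O 1.231 Å), giving the canonical 1.5 Å rise and ≈ 100°/residue
twist and consecutive Cα–Cα distances of 3.80 Å, aligns each helix with
the membrane normal, and arranges them antiparallel on a circle
(default radius 11.5 Å). Backbone N, CA, C, O are emitted so the
secondary-structure module can run on generated fixtures.

`sampleEnsemble()` draws Gaussian frames about the reference:

* `sigma` is the per-atom fluctuation SD *per Cartesian axis*, so the
  expected RMSF is σ√3. Values are chosen to straddle the qualitative
  regimes seen in receptor simulations — rigid helices below 1 Å RMSF,
  flexible loops above 2 Å — not to match any particular system.
* A correlation block (A, B, ρ) makes the atom union A ∪ B an
  **equicorrelated cluster** generated by one latent factor. This is the
  minimal positive-semidefinite structure with the stated cross-segment
  correlation: a matrix with ρ = 0.9 across blocks but 0 within them is
  not a correlation matrix at all. The planted N × N correlation is
  checked for PSD (eigenvalue floor −10⁻¹⁰) *before* any sampling, and the
  exact planted 3N × 3N covariance is returned with the trajectory.
* `drift` adds a random walk (per-axis step SD √(2 D dt)) to the atomic
  means, independently per atom by default, or shared per segment or
  globally. Per-atom diffusion is the default because a purely global
  random-walk translation would be removed exactly by frame-1 superposition
  and could never exercise the cosine-content diagnostic.
* Generation is a pure function of (spec, seed): the session RNG stream is
  saved and restored.

`makeMembraneBox()` places water, phosphate-like and methyl-like
pseudo-atoms uniformly in configured z-slabs (defaults: water beyond
±25 Å, phosphates in 15 < |z| < 25 Å, methyls in |z| < 10 Å, in a
60 × 60 × 80 Å box), redrawn independently per frame.

What the generator does **not** emulate: anharmonic and multi-basin
dynamics, real lipid conformations and protein–lipid coupling, solvent
structure, and time correlation within the Gaussian component (frames are
independent draws; only the drift term carries memory). Passing the
validation suite therefore demonstrates that the estimators recover known
first- and second-moment structure and graph topology — not that any
particular biological conclusion transfers to a specific receptor.

# The pipeline

`runStudy()` drives topology/trajectory loading, RMSF, secondary
structure (when backbone atoms are present), essential dynamics with
per-replica cosine content, DCCM → network → communities → connectivity,
and optional density/hydration, from a single config (R list or YAML), and
writes tidy CSV tables plus a JSON manifest echoing every parameter and
seed. Replica statistics follow the mean ± SD over {R0 window, R1, R2}
convention. All stages are deterministic given the config, so a rerun
reproduces every table byte for byte; stage failures abort with the stage
name while partial outputs remain on disk. `comparePhenotypes()` assembles
side-by-side RMSF and helix-count deltas, cosine-content and connectivity
tables, and a pairwise RMSF dissimilarity matrix.

The package is a library by design: the functions, `runStudy()` configs
and the repository's validation script are the interface, and no shell
entry point is shipped.

# Validation problem sizes

The validation suite and the repository's acceptance script use problem
sizes chosen to make Monte-Carlo error bounds meaningful at desk scale:
20 000-frame ensembles for 5%-level amplitude-recovery checks (the
relative SD of an RMSF estimate is ≈ (6 F)^{-1/2}), 70–105-atom bundles,
300-frame/100-ps-stride trajectories (a ~30 ns window at the network
stride) for the planted-partition runs with 20 seeds per condition, 50
seeds for the cosine-content median, and 40-frame membrane boxes for
density work. Exhaustive shortest-path enumeration backs the betweenness
kernel on all graphs up to 12 nodes.

# Known limitations

* XTC trajectories are not read (no R-side reader); DCD and the package's
  plain-text frame table are supported. Orthorhombic boxes only.
* Secondary structure never assigns E/S; π-helix detection uses the plain
  i→i+5 pattern without the priority subtleties of full DSSP.
* Girvan–Newman recomputes betweenness after every removal (exact, but
  O(E²·V) overall); networks of a few hundred residues are comfortable,
  whole-proteome graphs are not the target.
* The connectivity verdict depends on the community reporting threshold;
  with very small communities filtered out, weakly coupled segments can be
  declared unconnected even when individual edges exist.
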