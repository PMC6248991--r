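# HelixDynamics

Conformational-dynamics analysis of membrane-embedded helix-bundle
proteins from molecular-dynamics ensembles, for structural biologists and
simulation groups working on seven-transmembrane (GPCR-like)
architectures. Given a topology (PDB + segment definitions for TM1–TM7,
helix 8, loops) and a trajectory, the package computes the standard
post-processing battery — superposition and RMSD/RMSF with replica
statistics, secondary-structure accounting from backbone H-bond patterns,
contact maps and hydrogen-bond occupancies, membrane density profiles with
hydration integration — and the two collective-motion analyses at its
core:

* **Essential dynamics.** The mass-unweighted positional covariance
  C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩ of the Cα selection is eigen-decomposed;
  trajectories are projected on principal components, p_i(t) = v_i·(x(t)−⟨x⟩),
  and each projection is scored by its cosine content,
  CC = (2/T)(∫cos(πt/T) p dt)² / ∫p² dt ∈ [0, 1], the standard diagnostic
  for random-diffusion-like (unconverged) sampling. Motion fields span
  PC extremes and a dummy-variable regression parametrizes interface Cα
  motions across phenotypes/replicas.

* **Dynamical cross-correlation networks.** The DCCM
  c_ij = ⟨Δr_i·Δr_j⟩/√(⟨Δr_i²⟩⟨Δr_j²⟩) links residues with |c_ij| ≥ 0.7
  into a graph that is decomposed by the Girvan–Newman algorithm
  (iterative removal of the maximum-edge-betweenness edge, Brandes
  accumulation in compiled code, deterministic tie-breaking) while tracing
  the Newman–Girvan modularity Q = Σ_k (e_kk − a_k²); communities of ≥ 10
  Cα atoms are reported and inter-segment connectivity verdicts (e.g.
  TM2 ↔ TM5) are derived from community dominance and inter-community
  edges.

Because production MD trajectories are rarely redistributable, the package
ships a synthetic-ensemble generator that plants known ground truth —
per-atom fluctuation amplitudes, equicorrelated inter-segment blocks,
diffusive drift, membrane pseudo-atom slabs — so every estimator can be
validated against exact expectations. See the vignette
(`vignettes/transmembrane-dynamics.Rmd`) for the methods and design
rationale.

## Worked example

Plant a TM2–TM5 correlation block (ρ = 0.9) in a synthetic 7-helix
bundle, then recover it through the full DCCM → network → community →
connectivity chain:

```r
library(HelixDynamics)

bundle <- makeBundleReference(7, 15, atoms = "calpha")
bundle$topology
#> Topology: 105 atoms, 105 residues
#>   segments: TM1(15) TM2(15) TM3(15) TM4(15) TM5(15) TM6(15) TM7(15)

blocks <- data.frame(segmentA = "TM2", segmentB = "TM5", rho = 0.9)
functional <- sampleEnsemble(ensembleSpec(bundle, sigma = 0.4,
                                          blocks = blocks,
                                          nFrames = 300, dt = 100,
                                          seed = 42))
functional$trajectory
#> Trajectory: 300 frames x 105 atoms
#>   time 0..29900 ps

cm <- dccm(functional$trajectory, stridePs = 100)
cm
#> DCCM: 105 C-alpha nodes; off-diagonal range [-0.360, 0.831]

net <- girvanNewman(buildNetwork(cm, cutoff = 0.7, minSeqSeparation = 2))
net <- filterCommunities(net, 10)
connectivityReport(net, "TM2", "TM5")$connected
#> [1] TRUE
```

The 30 correlated TM2/TM5 Cα atoms form the single reported community
(30 nodes, 407 edges among them), so the two helices are declared
connected; rerunning with `blocks = NULL` yields only singleton
communities and `connected = FALSE`. The planted block is also visible
directly in the DCCM: the off-diagonal maximum (0.831) is the block
correlation after whole-set superposition. Convergence diagnostics read as
expected for a harmonic ensemble:

```r
m <- covarianceModel(functional$trajectory, stridePs = 4)
cosineContent(projectTrajectory(functional$trajectory, m, 1))
#> 5.88e-05  (values near 1 would indicate unconverged, diffusive sampling)
```

`runStudy()` drives the same chain — plus RMSF, secondary structure and
optional density/hydration stages — from a single config and writes tidy
CSVs with a JSON manifest; `comparePhenotypes()` assembles cross-phenotype
delta tables.

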