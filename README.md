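# dnapatch

Identify DNA-binding patches on protein surfaces from coarse-grained
molecular dynamics trajectories, rank them by their dissociation
kinetics, and quantify protein-induced DNA bending.

## The problem

Residue-resolution simulations of DNA-binding proteins (one bead per
amino acid at the C&alpha; position, three beads per nucleotide:
phosphate, sugar, base) produce trajectories in which short DNA
duplexes repeatedly associate with and dissociate from the protein
surface. Which surface residues form coherent binding sites, and how
strongly does each site hold DNA? `dnapatch` answers this with a
pipeline of four statistical stages:

1. **Contact calling.** Residue `r` contacts DNA copy `d` in a frame
   when the minimum distance from its bead to any bead of that copy is
   strictly below a threshold (default 8 Å, slightly above the Debye
   length at the simulated ionic strength). Distances honour the
   minimum-image convention in orthorhombic periodic boxes.
2. **Patch calling.** Residues are clustered by the Jaccard distance of
   their co-binding patterns,
   `dJ(i,j) = 1 − Intersection(i,j) / Union(i,j)`, where the
   intersection counts frames in which both residues contact the *same*
   DNA copy and the union counts frames in which either contacts any
   copy. Average-linkage hierarchical clustering cut at `dJ = 0.7`
   yields binding patches.
3. **Dissociation kinetics.** A binding event is a maximal run of
   frames in which at least one patch residue contacts the DNA copy of
   interest. Event lifetimes show two exponential regimes — transient
   encounters and stable binding. The survival curve
   `P(t) = N(t)/N0` is evaluated at time points chosen so the survivor
   counts form an arithmetic progression (equal weighting), and
   `ln P(t)` is fitted with a continuous two-segment model; the stable
   dissociation rate constant is `k_off = −slope` beyond the breakpoint
   `t1`. Mean and error of `k_off` come from 1000 bootstrap resamples
   of the events. Patches are named by system label + affinity rank
   (rank 1 = smallest `k_off`) and classified strong/weak at
   `2.0e-5` per timestep.
4. **DNA bending.** Four anchor beads define a projection plane
   (normal to the plane of the two coiled-coil arms, aligned with their
   bisector). The bending angle θ is the angle between the projected
   chords of the two strands, each taken between the sugar beads of
   nucleotides 1 and 11 from the 5′ end (one helical turn, so the chord
   tracks the duplex axis). Per-trajectory means — after discarding the
   first half of each trajectory and excluding dissociated trajectories
   — are compared between conditions with Welch's t-test.

A synthetic-trajectory generator (`generate_dwell_times`,
`generate_contact_tensor`, `generate_bent_dna`,
`generate_binding_trajectory`) produces inputs with known kinetics,
planted patches and planted bends, so every stage is validated against
ground truth.

## Worked example

```r
library(dnapatch)

# a synthetic system: 40 residues, two planted patches with slow rates
# 4e-6 and 1e-5 per timestep, two DNA copies in a 200 A periodic box
patches <- list(1:5, 11:15)
cloud <- make_protein_cloud(40, patches, seed = 1)
kin <- list(kinetic_spec(1e-3, 4e-6, 0.7), kinetic_spec(1e-3, 1e-5, 0.7))
spec <- contact_schedule_spec(40, patches, n_frames = 6000,
                              n_dna_copies = 2, kinetics = kin,
                              binding_rate = 0.1, seed = 6)
traj <- generate_binding_trajectory(cloud, spec, box_side = 200)

tensors <- list(call_contacts(traj$coords, traj$topology, threshold = 8))
ps <- cluster_patches(jaccard_distances(tensors))
ests <- lapply(ps$patches, function(res)
  bootstrap_koff(extract_events(tensors, res), B = 200, seed = 12))
rank_patches(ps, ests, label = "A")
#> <patch_set> 2 patches, 0 unassigned residues
#>   A1  koff 3.43e-06  [strong] (5 residues)
#>   A2  koff 1.42e-05  [strong] (5 residues)
```

The two planted patches are recovered exactly; the slower patch
(planted 4e-6, estimated 3.4e-6 per timestep) is ranked A1 and both
rates fall below the 2.0e-5 strength cutoff. The same stages run from
files via `run_pipeline()` with a YAML configuration; see the methods
vignette (`vignettes/patch-calling-and-kinetics.Rmd`) for the model
details and parameter guidance.

Bending-angle comparison from per-trajectory summary statistics:

```r
compare_conditions(c(mean = 31.0, sd = 14.5, n = 20),
                   c(mean = 3.1, sd = 7.6, n = 4))
#> <angle_comparison> welch t = 5.585, df = 8.266, p = 0.000462
```

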