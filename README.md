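# icetraj

Quantitative analysis of seeded ice-growth trajectories in the presence
of small zwitterionic solutes — the computational workflow behind the
question of why α-alanine inhibits ice recrystallization while its
isomer β-alanine does not.

The package is aimed at molecular-simulation practitioners studying ice
recrystallization inhibition (IRI) by small molecules. The simulated
system is an ice Ih slab exposing a chosen crystallographic face
(basal {0001}, primary prismatic {10-10} or secondary prismatic
{11-20}) to two adjacent liquid slabs, growing along ±z. From a
trajectory, `icetraj` computes:

- **Ice/liquid labels** per water molecule from a multi-stage
  neighbour-averaged Steinhardt *q̄₆* bond-order parameter
  (O–O cutoff 3.5 Å), with a threshold calibrated from single-phase
  samples and a first-shell majority-vote cleanup.
- **Seeded-cluster growth**: the size *N(t)* of the connected ice
  cluster containing the original seed is converted to an equivalent
  slab thickness *h(t) = N(t)·v_mol / (2·A_xy)* (two growing fronts)
  and its least-squares slope is the growth rate in m/s, with *v_mol*
  measured from the trajectory's own seed lattice.
- **Outcome classification** per trajectory: `OG` if a solute ends up
  buried at least ~8 Å (two molecular layers) below the front, else
  `IRI` if the growth rate is below 0.03 m/s, else `no_IRI`; counts are
  aggregated per (solute, face, concentration) group.
- **Interaction metrics**: hydrogen bonds by functional group
  (carboxylate acceptor / ammonium donor, 3.5 Å / 30° criterion),
  hydration index (first-shell waters per van der Waals volume,
  molecules/Å³), grid-based molecular volume, Shrake–Rupley SASA, and
  the carboxylate-rotation dihedral distribution.
- **Lattice compatibility**: solute N–O distance distributions against
  the ice O–O lattice reference, and O···O···O / O···N···O angle
  distributions for the three nearest waters, each summarised with a
  histogram-intersection overlap score.
- **Free-energy estimators**: well-tempered metadynamics on a 1D
  periodic (dihedral) collective variable with FES reconstruction
  `F = −γ/(γ−1)·V_bias`, and the Bennett acceptance ratio for ΔF from
  forward/reverse work samples — both validated against analytic
  oracles.

Because no trajectories are deposited with the study this workflow
mirrors, the package includes a first-class synthetic generator:
ice slab + liquid slabs + fronts advancing at a scripted velocity, with
solutes following scripted fates (overgrown / rejected / bulk liquid)
and full per-frame ground truth. Every analysis stage is tested against
that ground truth.

## Worked example

Generate a prismatic-face trajectory in which an α-alanine molecule per
liquid slab is overgrown by a front advancing at 0.08 m/s, then run the
full growth analysis:

```r
library(icetraj)

spec <- lattice_spec("primary_prismatic", nx = 3, ny = 2, nz = 2)

# calibrate the ice/liquid threshold from single-phase samples
cal <- calibration_samples(spec)
threshold <- calibrate_threshold(cal$ice, cal$liquid)   # 0.296

script <- growth_script(front_velocity = 0.08, n_solutes_per_slab = 1,
                        solute_fates = list(solute_fate("overgrown",
                                                        depth = 16)),
                        seed = 1)
run <- generate_growth_trajectory(spec, script, n_frames = 40, dt = 0.9)
labels <- label_trajectory(run$trajectory, threshold,
                           run$ground_truth$seed_region)
result <- analyze_growth(run$trajectory, labels)
result
#> growth result: rate 0.0765 m/s, depth 14.0 A, outcome OG (bind frame 11)
aggregate_outcomes(list(result), face = "primary_prismatic")
#> Outcomes (OG / IRI / no-IRI):
#>   alpha_alanine  primary_prismatic    (2 solute) : 1 / 0 / 0
```

The scripted velocity (0.08 m/s) is recovered within a few percent, the
solute scripted to be buried 16 Å deep is measured ~14 Å below the
(conservatively placed) front, and the trajectory is classified
overgrown. `run_pipeline()` applies the same stages over a manifest of
many trajectories and `control_baseline()` reports percent rate
reductions against solute-free controls — the quantity behind the
0.03 m/s inhibition cutoff (≈50% reduction versus typical controls).

The isomer geometry comparison runs without any trajectory:

```r
conformer_ensemble_compare(n_samples = 2000, seed = 1)
# mean volumes ~83.9 (alpha) vs ~82.0 (beta) A^3  -> 2.4% apart
# mean SASA    ~248  (alpha) vs ~247  (beta) A^2  -> 0.4% apart
```

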