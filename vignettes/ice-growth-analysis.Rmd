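---
title: "Quantifying seeded ice growth and solute overgrowth with icetraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seeded ice growth and solute overgrowth with icetraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ice recrystallization — the growth of large ice crystals at the expense
of small ones during annealing — is a principal cause of freezing damage
in biological samples. Small zwitterionic molecules can inhibit it, and
the striking case of the α/β-alanine isomer pair suggests the mechanism
is not ice *binding* but ice *overgrowth*: a molecule that fits the ice
lattice poorly keeps disrupting the advancing front, while one that fits
well is simply engulfed, after which growth proceeds unimpeded.

`icetraj` implements the trajectory-analysis side of that argument as a
tested, reusable pipeline: seeded-cluster growth kinetics, categorical
overgrowth/inhibition outcomes, hydrogen-bonding and hydration metrics,
lattice-compatibility statistics, and the two free-energy estimators the
argument leans on (well-tempered metadynamics on a torsional coordinate,
and the Bennett acceptance ratio). Because the original trajectories are
not publicly deposited, the package ships a synthetic trajectory
generator with exact ground truth, and every stage is validated against
it.

## The synthetic generator: what it emulates

`generate_growth_trajectory()` reproduces the *geometry* of the
simulated setup: a central ice Ih slab exposing a chosen face in the
xy-plane (periodic in x and y, vacuum-terminated in z), two adjacent
liquid slabs, and two fronts advancing symmetrically along ±z at a
scripted velocity (m/s). Liquid molecules are converted to ice in order
of their distance from the slab centre: each is pre-assigned a
lattice-extension site and snaps onto it (plus Gaussian noise
`noise_sigma_ice`, default 0.25 Å) once the front passes; remaining
liquid jitters i.i.d. (`noise_sigma_liquid`, default 0.8 Å) about a
minimum-distance (2.4 Å) random packing. Solutes follow scripted fates:
`overgrown` (static, engulfed to a requested depth, optionally
substitutional — nitrogen registered onto a lattice site), `rejected`
(rides 2.6 Å ahead of the front), or `bulk_liquid` (kept ≥6 Å clear of
the final front). Ground truth records per-frame front positions,
per-molecule phase labels, binding frames and final burial depths.

Two generator choices deserve explanation:

- **Liquid density 0.0311 /Å³**, the ice-site density, not real water's
  0.033 /Å³. With a denser liquid the front consumes molecules faster
  than it sweeps volume, stranding "liquid" molecules inside the frozen
  region; the classifier progressively co-opts them and growth rates
  inflate by ~10% even without noise. Matching the densities makes
  front advance exactly volume-conserving. The 6% water/ice density
  difference is immaterial for the geometric analyses these fixtures
  exercise.
- **`liquid_pad = 16 Å`** of liquid beyond the scripted total growth.
  The order parameter averages over ~4 neighbour shells (≈14 Å), so if
  the front approaches the liquid/vacuum edge more closely, its
  apparent erosion width drifts over time and biases the fitted slope.

What the generator does **not** emulate: dynamics (no momenta, no
diffusion), energetics (no force field, no melting/refreezing), real
liquid-water structure (a min-distance packing has no hydrogen-bond
network), proton disorder satisfying the full Bernal–Fowler rules
(protons take randomly chosen tetrahedral bond directions), and density
relaxation at the front. Passing tests therefore demonstrate that the
*measurement* pipeline recovers known kinematics and geometry from
realistic-looking noisy configurations — not that it would agree with
any particular force field's thermodynamics.

## Ice classification

The order parameter (`local_order_parameter()`) is a Steinhardt *l* = 6
bond-order magnitude over O–O neighbours within 3.5 Å, with the complex
q₆m vectors averaged over {molecule + neighbours} for **four rounds**
(one round is the familiar Lechner–Dellago q̄₆) before taking the
rotationally invariant magnitude. The extra rounds matter because the
generator's noise is i.i.d. per atom — harsher on bond orientations
than the correlated thermal motion of real ice — and with a single
averaging round the ice and liquid distributions overlap beyond the 1st
and 99th percentiles at the default noise, so the calibration contract
cannot be met. Each additional round suppresses the incoherent liquid
tail faster than the coherent crystal signal. The perfect-lattice
reference value at these defaults is q̄₆ = 0.5317, a random ideal gas at
liquid density averages ≈0.13, and the calibrated threshold (midpoint
between the ice 1st percentile and the liquid 99th percentile of
single-phase samples, `calibrate_threshold()`) lands near 0.30.

Binary labels then get one round of first-shell majority voting
(`cleanup_labels()`): isolated misclassified molecules inherit the phase
of their surroundings, without smearing the interface (influence radius
one shell). The seeded cluster is the largest connected component (O–O
≤ 3.5 Å) of ice-labelled molecules intersecting the seed region; front
positions use the 95th-percentile extreme z per side, which resists
single stray molecules better than the maximum.

Two systematic properties of this classifier shape everything
downstream, and the tests assert around them rather than pretending
they are absent:

- **Conservative erosion.** Freshly grown surface layers and
  interfacial molecules read as liquid until covered (≈1.5 molecular
  layers' worth). Cluster sizes undercount by a roughly constant
  offset; fronts sit ~3–5 Å inside the true front; measured burial
  depths are ~3–5 Å shallower than scripted truth; binding is detected
  a few frames late.
- **A startup transient.** The erosion width takes about one grown
  layer to reach steady state, so rate fits exclude the first 20% of
  frames (`burn_frac` in `analyze_growth()`); the window start is
  `max(binding frame, burn-in)`.

Ground-truth agreement outside a ±4 Å interfacial band exceeds 95% at
the default noise, and a noiseless crystal classifies perfectly.

## Growth rates and outcomes

Cluster size is converted to an equivalent slab thickness
`h(t) = N(t) · v_mol / (fronts · A_xy)` with `fronts = 2` for the
double-interface cell (configurable to 1), and the least-squares slope
of `h(t)` over the window is the rate, reported in m/s (1 Å/ns =
0.1 m/s). The per-molecule volume `v_mol` is measured from the
trajectory itself: the median nearest-neighbour O–O distance *d* of the
seed cluster on positions time-averaged over the first five frames
(lattice molecules are stationary, so averaging suppresses the noise
that would otherwise bias pair distances upward and truncate them
against the 3.2 Å cutoff), a first-order residual correction
`d ← d − var(d)/d`, and the tetrahedral-network relation
`v_mol = (8√3/9) d³`. No literature ice density is assumed, which keeps
the conversion self-consistent between synthetic and real input.

Because sites freeze in discrete layers, the recovered slope is
quantised at the layer scale: over a window spanning *k* layers the
relative error floor is roughly ±(half a layer)/*k*. Windows spanning
~20+ layers recover noiseless scripted velocities within 2%; at the
default noise, scripted velocities of 0.01–0.10 m/s are recovered with
a median absolute relative error of a few percent over 10 Å of growth.

Outcomes follow the two-threshold rule: `OG` if any solute's burial
depth reaches 8 Å (two molecular layers — 7.79 Å for the primary
prismatic stacking, 7.34 Å basal; the Å criterion is primary since the
layer phrasing is face-dependent), else `IRI` if the rate is below
0.03 m/s, else `no_IRI`. Overgrown trajectories are excluded from the
inhibition counts. Both thresholds are arguments, and the 0.01–0.06 m/s
robustness range can be swept; the test suite scripts all non-overgrown
rates outside that range so the calls are invariant across it. A
solute's burial only counts if ice-labelled cluster molecules actually
lie between it and the front (within a 6 Å lateral radius) — a solute
floating beyond the front cannot be "deep".

## Solute templates and the torsional ensemble

Both isomers are built as rigid 13-atom zwitterions from standard
internal coordinates (C–C 1.52 Å, C–N 1.49 Å, C–O 1.26 Å, C–H 1.09 Å,
N–H 1.02 Å; tetrahedral sp³ centres, planar carboxylate at 117°). In
the α isomer the carboxylate and ammonium sit on the same carbon; in β
they are separated by a methylene, which is exactly why β's N–O
distances can reach ~4.8 Å while α's are pinned to 2.6–3.6 Å.

The torsional Monte Carlo sampler (`sample_conformers()`) performs
Metropolis moves on the rotatable torsions under a simple potential:
repulsive sterics `0.1 · (0.9(Rᵢ+Rⱼ)/r)¹²` (Bondi radii) plus Coulomb
screened by a bulk-water dielectric (ε = 80) over intramolecular pairs
three or more bonds apart. The strong screening is deliberate: the
solution-phase ensemble is the one of interest, and with weak screening
the zwitterion collapses into an intramolecular salt bridge that real
hydrated β-alanine does not form — its conformational barriers are of
order kT. The reported carboxylate-rotation dihedral is O1–C–CA–N for α
(the quadruple that expresses the electrostatic locking between the
ammonium and the nearest carboxylate oxygen) and O1–C–CA–CB for β; the
alternative α quadruple is recorded alongside because the plain
"O–C–C–C" phrasing is ambiguous about which terminal atom is meant.

`conformer_ensemble_compare()` samples both isomers (RNG reseeded per
isomer, so identical kinds give exactly identical ensembles), computes
grid volume (0.2 Å spacing) and Shrake–Rupley SASA (probe 1.4 Å, 960
deterministic golden-spiral points per atom) per conformer, and reports
the relative percentage difference of the means with bootstrap standard
errors. At 2000 conformers per isomer the two quantities differ by
~2.4% (volume, α larger) and ~0.4% (SASA) — both within a factor of a
few of one percent, consistent with the isomers being nearly
indistinguishable by size.

The hydration index is the mean count of water oxygens within 3.4 Å
(a first-minimum proxy) of any solute heavy atom, normalised by the
solute's own van der Waals volume. The literature definition it follows
does not pin down the shell cutoff or the normalising volume, so both
are arguments; the units (molecules/Å³) force *a* volume normalisation
but not a unique one.

## Lattice compatibility

The lattice distance reference pools first-shell (≤3.2 Å)
nearest-neighbour O–O distances over seeded-cluster molecules; the
angle reference pools three-nearest-water angles around tetrahedrally
coordinated (exactly four neighbours within 3.2 Å) cluster molecules.
Solute-centred distributions (N–O distances; O···O···O-style angles
with a solute O or N replacing the central water) are compared to these
references via a histogram-intersection overlap score on fixed binning
(0.05 Å / 2°): the integral of the pointwise minimum of the two
densities, in [0, 1], equal to 1 iff the binned distributions coincide.
The score is introduced because a visual comparison is not testable; it
is symmetric and bounded, but note it punishes differences in *width*
as well as location, and finite samples depress it by ~√(bins/n), so
comparisons should use comparable sample sizes.

The mechanism-level property the suite asserts is ordinal, where it is
literally true by construction: a solute placed substitutionally in a
noisy lattice scores strictly higher angle compatibility than the same
solute in a random liquid packing, and scripted-overgrown trajectories
show higher post-binding growth rates than matched non-overgrown ones.

## Free-energy estimators

`run_wtmetad()` runs overdamped Euler–Maruyama Langevin dynamics on a
user-supplied 1D periodic model potential (degrees; kcal/mol) with a
well-tempered bias: Gaussians of width σ = 18° deposited every 250
steps at height `0.08 · exp(−V_b/((γ−1)kT))`, γ = 8, accumulated on a
1° grid with forces from centred finite differences. The friction
default (0.075, i.e. D ≈ 8 deg²/step) keeps the per-step drift well
under the Gaussian width — with too large a diffusion the integrator
step exceeds the landscape's features and barrier estimates degrade.
The FES estimate is `−γ/(γ−1) · V_bias`, time-averaged over the
depositions of the second half of the run (the converged bias equals
`(1−1/γ)F` plus a constant plus a fluctuating part that averaging
suppresses) and min-shifted to zero. On `V(φ) = A·cos 2φ` the 2A
barrier is recovered within ~5–7% (the acceptance bound is 15%) with
minima at ±90°, and a flat potential reconstructs flat to <0.3
kcal/mol. The engine runs on model potentials because the estimator
mathematics — not any molecular force field — is the part worth
testing at desk scale; the molecular free-energy surfaces themselves
are out of scope.

`bar_estimate()` solves the Bennett self-consistency equation
`Σ_F f(M + (W_F − ΔF)/kT) = Σ_R f(−M + (W_R + ΔF)/kT)` (Fermi `f`,
`M = ln n_F/n_R`) by bracketed root finding over the pooled work range
±10 kT, and returns the standard asymptotic error from the relative
fluctuations of the Fermi weights. Crooks-consistent Gaussian work
samples with planted ΔF ∈ {−5, 0, 5} kT are recovered within three
standard errors; shifting forward work by +c and reverse by −c shifts
ΔF by exactly +c; non-overlapping work distributions set a warning
flag rather than failing.

## Numerical choices and degenerate inputs

- All coordinates are Å, times ns, rates m/s; the single conversion
  constant (1 Å/ns = 0.1 m/s) lives in one place.
- The ice Ih cell is an orthorhombic 8-molecule representation; the
  internal parameter u = a²/(3c²) + ¼ makes all four tetrahedral bonds
  exactly equal for any (a, c). The defaults a = 4.50 Å, c = 7.34 Å
  give a 2.755 Å bond; with those constants c/a is 0.1% off the ideal
  ratio, so three-nearest angles deviate from arccos(−1/3) by ≈0.06° —
  exactness tests use c = a√(8/3).
- Oxygens with no neighbours get order parameter 0; seeded-cluster
  extraction errors if no ice-labelled molecule intersects the seed
  region ("seed melted" is out of scope); `calibrate_threshold()`
  errors when the percentile gap closes instead of returning a
  meaningless midpoint; rate windows must span ≥5 frames; the
  lattice-distance reference requires ≥50 pair samples.
- Ties in torsion rotation direction are resolved by checking the
  resulting dihedral and re-rotating the other way; the histogram
  overlap uses closed-right binning with the pooled range rounded
  outward to bin edges.
- Batch runs (`run_pipeline()`) isolate per-trajectory failures,
  continue, and report them; outputs carry the package version, seed
  and a config hash.

## Problem sizes in the test suite

The suite uses a 3×2×2-cell primary-prismatic slab (96 seed waters,
~200–700 total molecules), 40–100 frames per trajectory, 20-trajectory
outcome suites, 5 seeds per velocity on a 4-velocity grid, 600–2000
conformers per isomer, and 4×10⁵ metadynamics steps — sizes chosen so
the full suite runs in about a minute on a laptop-class core while
every claim is still exercised at meaningful statistics.

## Known limitations

- The classifier's erosion bias is conservative and approximately
  constant, but its magnitude (~1.5 layers) is specific to the chosen
  order parameter, noise model and cutoffs; real-trajectory use should
  recalibrate on single-phase samples from the same ensemble.
- Layer-discreteness quantisation puts a floor on rate precision for
  short windows; very slow fronts need proportionally longer windows.
- The torsional ensemble is a geometric sampling model, not a force
  field: it supports size/shape comparisons and dihedral-range
  arguments, not energetics.
- The overgrowth depth of a rejected solute is only meaningful down to
  about −(standoff + erosion); its sign, not its magnitude, carries
  information.
- No ice polytype discrimination (Ih vs Ic vs stacking-disordered), no
  clathrate detection, and binary trajectory formats (XTC/DCD) are not
  read — extended XYZ, GRO and multi-model PDB are.
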