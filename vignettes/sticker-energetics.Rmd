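---
title: "Sticker energetics in condensates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sticker energetics in condensates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condx)
```

## What this package computes

Aromatic residues act as the main adhesive "stickers" in many biomolecular
condensates, and experiments consistently rank tyrosine above phenylalanine
in sticking strength — the opposite of what hydrophobicity scales and
folded-protein contact statistics suggest. `condx` implements the analysis
chain that resolves this tension: it measures how favourable it is to move
a Tyr- versus a Phe-containing peptide into a given medium (the transfer
free energy), characterises the media themselves (phase diagrams, dielectric
constants, contact geometry), and combines quantum-derived interaction
energies with solvation terms into a contact-energy decomposition whose
balance flips with the dielectric constant of the environment.

Every stage has a synthetic generator that plants known ground truth, so
the full pipeline is exercised end to end without any simulation data.

## Free energies from non-equilibrium switching work

An alchemical mutation interpolates the Hamiltonian between Phe
(coupling parameter 0) and Tyr (coupling parameter 1). Each short driven
switch yields a work value, the integral of the Hamiltonian derivative over
the coupling parameter, computed here by trapezoidal quadrature
(`integrate_work()`). Given forward and backward work samples, Bennett's
acceptance ratio (`bar_estimate()`) solves the implicit maximum-likelihood
equation equating the forward and backward Fermi-function sums. The
equation is monotone in the free energy, so we use bisection on a bracket
spanning both work distributions (tolerance 1e-8 kJ/mol): slower than
Newton steps but immune to the saturation plateaus of the logistic terms.
When the forward and mirrored backward work distributions share no support
(gap above 10 kT) the estimate would be an extrapolation, and the function
refuses with a diagnostic naming both work ranges rather than returning a
number.

Errors come from bootstrap resampling (default 1000 resamples, forward and
backward resampled independently); when independent replicate trajectories
exist, `replicate_mean_cycle()` instead reports the standard error of the
mean across replicates. The Crooks fluctuation theorem provides a built-in
diagnostic: the forward work density and the mirrored backward density must
cross at the free-energy difference, and `crooks_crossing()` locates that
crossing by piecewise-linear interpolation of the two histograms.

The transfer cycle (`ddg_transfer()`) subtracts the mutation free energy in
water from the one in the medium; a negative difference means the medium
prefers the Tyr variant. The synthetic generator `gen_crooks_work()` draws
both work sets from the Gaussian pair that satisfies the Crooks relation
exactly — forward works centred at the free energy plus the dissipation,
backward works mirrored, both with variance 2 kT times the dissipation —
so the planted free energy is recoverable by construction, and estimator
bias is measurable. Defaults follow typical switching campaigns: 100
switches per direction, 298 K, kB = 0.00831446 kJ/mol/K. Upstream
protocols sometimes discard a burn-in of 100-200 ns before selecting
snapshots; since no fixed rule decides the amount, burn-in handling is the
caller's responsibility and not hard-coded anywhere.

## Slab phase diagrams

Direct-coexistence (slab) configurations are reduced to density profiles
along the longest box axis (`density_profile()`, default bin 0.1 nm, units
mg/mL). Each frame is first recentred so the periodic centre of mass of all
particles sits at the box middle — computed with the circular-mean
construction, which is exact under periodic boundaries — because the
symmetric two-phase profile assumes a centred slab and slabs drift over a
trajectory. The profile is fit jointly over both half-boxes through |x| to

rho(x) = (rho_L + rho_H)/2 + (rho_L - rho_H)/2 * tanh((|x| - x_DS)/t),

giving the dilute and dense densities and the position and width of the
dividing surface (`fit_tanh()`, Levenberg-Marquardt with percentile-based
initial guesses). Fitting through |x| rather than averaging the two halves
first makes no difference for symmetric data but uses all bins in one
covariance estimate. A profile whose dense/dilute gap is indistinguishable
from zero reports `converged = FALSE` instead of raising: a single-phase
state is a result, not an error.

Across a temperature scan (`coexistence_scan()`), a point is usable when
the fit converged, the gap exceeds 100 mg/mL and both branch densities have
relative errors under 50%. These thresholds make the qualitative notion of
"clearly distinguishable phases" machine-checkable; they are deliberately
conservative so that near-critical profiles drop out rather than bias the
critical fit. The critical point is then extracted in two stages
(`fit_critical()`): the order parameter rho_H - rho_L is fit to
A (Tc - T)^beta with the 3D-Ising exponent beta = 0.325 held fixed (it is
never a free parameter), and with Tc known, the law of rectilinear
diameters — the mean of the coexisting densities is linear in Tc - T —
gives the critical density by linear regression. The two-stage order
mirrors how these fits are reported in the simulation literature and keeps
the rectilinear fit linear.

The slab generator places one pseudo-particle per residue (mass 120 g/mol,
roughly a Gly/Ser-scale residue) by rejection sampling against the planted
profile in a 20 x 4.5 x 4.5 nm box. Densities in mg/mL follow from the
particle masses and Avogadro's number; since residue-to-mass conventions
vary, the generator documents its own (mass is a parameter).

## Dielectric constant

The static dielectric constant follows from equilibrium box-dipole
fluctuations,

eps = 1 + (<M^2> - <M>^2) / (3 eps0 kB T <V>),

with all quantities converted to SI internally (`dielectric_constant()`).
Conversion constants are pinned (e = 1.602176634e-19 C,
1 D = 3.33564e-30 C m, eps0 = 8.8541878128e-12 F/m) so results are
bit-reproducible. Errors use blocking (`blocking_error()`, default 5
contiguous blocks, each at least 2 frames): the per-block estimates absorb
the slow dipole autocorrelation that a naive per-frame error ignores. The
dipole series is consumed as given — whether it covers a whole solvated
system or an isolated dense phase is the caller's labelling decision — and
`box_dipole()` can build it from charged frames when needed. The generator
plants iid Gaussian dipole components whose variance makes the formula hit
a target dielectric in expectation; real dipole series are autocorrelated,
so passing the iid recovery test validates the estimator's algebra, not its
behaviour under slow sampling.

## Contact geometry

Contact matrices (`contact_matrix()`) declare two residues in contact when
any inter-particle distance falls at or below the cutoff under minimum
image. The cutoff defaults to 0.45 nm — a common heavy-atom contact
distance — and is recorded in the output because reported contact maps are
sensitive to it. Counts are normalized by the number of available molecule
pairs and then by the matrix maximum, giving values in [0, 1]; the raw
per-frame counts are returned alongside since normalization conventions
differ between studies.

Aromatic ring pairs are characterised by centroid distance and the angle
between ring-plane normals (`ring_geometry()`). Normals are oriented by the
ordered ring vertices (Newell's construction), so theta spans the full
[0, pi]: near 0 or pi means stacked, near pi/2 T-shaped. Amide-ring
(sp2-pi) pairs use the plane through the three amide atoms with the same
distance/angle contract (`sp2_pi_geometry()`). The reporting cutoff for
pair maps defaults to 0.9 nm centroid-centroid; 2-D (distance, theta)
histograms use 0.02 nm x 5 degree bins.

Radial distribution functions (`rdf()`) normalize the minimum-image pair
histogram by the exact spherical shell volume and the ideal-gas pair
density; the uniform generator `gen_ideal_gas()` is the g(r) = 1 oracle,
and both the contact and rdf paths are tested for exact agreement with
brute-force O(N^2) loops. SASA uses Shrake-Rupley with a golden-spiral
point grid (default 960 points, probe 0.14 nm, bundled Bondi-style radii);
the test points are distributed per atom in the lab frame, so SASA is exact
under translation and rotation-invariant only up to the grid
discretization, which falls below 1% of the isolated-sphere area at the
default point count.

## Contact-energy decomposition and the crossover

Contact formation between two monomers in a medium decomposes into the
transfer of each monomer from water into that medium plus their interaction
there:

dE_contact = dE_int + dG_transfer_i + dG_transfer_j,

with dE_int = E_dimer - (E_i + E_j) from electronic energies and
dG_transfer from solvation free energies relative to water. The package
consumes these as tables (CSV schemas in `read_energy_tables()`); computing
them is upstream quantum chemistry and out of scope. Side-chain analogues
follow the standard choices: p-cresol for Tyr, toluene for Phe,
N-methyl-acetamide for the amide group.

Differences against a reference pair (conventionally the pi-stacked
F-F cross dimer, re-evaluated per solvent) yield ddE curves versus the
solvent dielectric constant. `find_crossover()` locates sign changes by
piecewise-linear interpolation in eps — recorded in the output metadata,
since curves read off plots depend on the interpolation — and crossovers
are reported strictly per solvent class: aliphatic solvents, alcohols and
water-like media behave differently, and a root interpolated across classes
would be meaningless. The synthetic table generator plants
dE_int = a + b/eps and dG_transfer = p + q/eps, making every ddE curve a
rational function whose root is analytic; tests verify the reported
crossover converges to that root as the eps grid refines. Setting every q
to zero (dielectric-independent transfer) leaves the sign of ddE fixed
across the grid in the planted model — the package-level restatement of the
finding that the transfer term, not the interaction energy, drives the
Tyr/Phe crossover. Energy tables are fixed to kJ/mol; kcal/mol input is
accepted only with an explicit unit column (factor 4.184).

Bundled reference tables (`reference_lookup()`) ship as versioned CSV with
citation strings: Miyazawa-Jernigan diagonal contact energies
(F-F -7.26 RT, Y-Y -4.17 RT), aqueous solubilities at 25 C (Tyr 0.045,
Phe 2.79 g/100 g water), water-model dielectric constants, and the
Kyte-Doolittle hydropathy scale for `minmax_normalize()`. User tables are
never merged silently with the bundled ones.

## Pipeline, determinism and problem sizes

`run_config()` executes YAML-declared stages through the functions above;
every JSON artifact carries the config hash (MD5 of the canonical JSON
serialization), the seed and the package version, and identical configs
produce byte-identical numeric outputs. A thin command-line wrapper
(`inst/scripts/condx`) exposes the same stages for shell use.

All generators are pure functions of their parameters and seed. The test
suite and the acceptance script run at desk scale: 5000 work values per
direction for BAR recovery, 100 slab frames of ~2000 pseudo-particles,
1e5 dipole frames, 8 coexistence temperatures with 5 mg/mL noise, 200-point
dielectric grids. These sizes put counting noise well below the 3-sigma
recovery bands used in the checks while keeping the whole suite in tens of
seconds. Headline literature values from microsecond MD and DFT campaigns
(transfer free-energy differences of a few kJ/mol in peptide condensates,
condensate dielectric constants of 30-50) are context for interpreting
output signs and magnitudes, not quantities this package can reproduce from
synthetic input.

## Known limitations

- The synthetic slab generator draws particles independently per frame;
  real trajectories are time-correlated, so planted-recovery tests do not
  probe equilibration or drift diagnostics.
- The dipole generator is iid; blocking on it reproduces the naive error,
  so the blocking machinery's benefit on correlated data is asserted only
  structurally.
- Geometry operations assume orthorhombic boxes and whole molecules within
  a residue group (groups are made whole by minimum image relative to
  their first atom).
- BAR assumes the two work sets come from the same pair of end states at a
  common temperature; no consistency check across temperatures is
  attempted.
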