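---
title: "Methods behind actdyn: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind actdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actdyn)
```

`actdyn` implements the trajectory-analysis toolchain used to
characterize the intrinsic dynamics of small protein domains — in
particular the regulatory ACT domain of phenylalanine hydroxylase (PAH),
whose mobile loop regions interconvert between an open and a closed
arrangement that modulates the solvent exposure of a hydrophobic,
putatively ligand-binding surface. This vignette explains each model the
package implements, the tunable parameters and why their defaults are
what they are, the synthetic-data generators and what they do and do not
emulate, and the numerical conventions that make results reproducible.

## Superposition, RMSD and RMSF

Every downstream analysis assumes internal motion has been separated
from rigid-body motion. `kabsch_fit()` solves the least-squares
superposition problem by SVD of the 3×3 cross-covariance of centered
coordinates, with the standard reflection correction so the returned
rotation always has determinant +1; degenerate inputs (fewer than three
atoms, collinear selections) are hard errors rather than silently
unstable answers. `fit_trajectory()` applies the fit per frame.

Two conventions matter and are fixed deliberately:

* **The reference is the starting structure**, not the average. Fitting
  to an iteratively refined average is available
  (`iterate_average = TRUE`) but off by default, because fluctuation
  profiles are conventionally quoted about the initial model.
* **Uniform weights.** No mass weighting: the analyses this package
  reproduces are Cα-only, where per-atom masses are identical anyway;
  stating the convention keeps eigenvalue scales comparable.

`rmsf()` returns per-atom root-mean-square fluctuations
`RMSF_i = sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)`. A useful exact identity links
it to essential dynamics: the sum of squared RMSF values equals the
trace of the positional covariance matrix computed from the same frames.
The test suite asserts this identity at 1e-10 relative tolerance.

## Essential dynamics

`covariance_matrix()` builds the 3N×3N covariance of the selected atoms
with **population (1/n) normalization**. The choice is invisible to
variance *fractions* but changes absolute eigenvalues, so it is
documented and fixed; anyone comparing against a 1/(n−1) implementation
should expect a factor (n−1)/n on the eigenvalues.

`pca_modes()` diagonalizes the symmetrized matrix. Eigenvector signs are
intrinsically arbitrary; the package makes the largest-magnitude
component of each mode positive so that projections are reproducible
across platforms. Small negative eigenvalues from floating-point noise
are clipped at −1e-10; anything below that is treated as an input error.

`combined_ed()` implements the combined (multi-system) variant: each
trajectory is reduced to a common equivalent-atom set — for homologous
systems, through an `atom_map()` built from a sequence alignment — and
all frames are pooled with **equal per-frame weight**, so longer
trajectories contribute proportionally more, matching the idea of
concatenating trajectories into one pseudo-trajectory. Projections of
each system are computed against the **pooled mean** (the standard
choice; per-system means would remove exactly the between-system
differences the method is meant to expose). Frames are superposed on a
single common reference over the mapped atoms before pooling
(`fit = TRUE`); generators that already work in a common frame can skip
this.

## Correlation webs

`dccm()` computes the per-atom normalized covariance
`C_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`; atoms with zero
positional variance yield 0 entries with a warning rather than NaN.
`correlation_web()` keeps pairs with `C_ij` **strictly greater** than
the threshold (default 0.3, the conventional cutoff for this analysis),
using the *signed* correlation by default; an `absolute = TRUE` mode is
available for workflows that treat anticorrelation as connectivity.
Sequence neighbours with `|i−j| ≤ 2` are excluded by default because
covalently tethered neighbours are trivially correlated; the setting is
reported inside the returned object so any published link count can name
it. `count_cross_links()` then counts edges bridging helix (H) and
strand (E) residues, a compact summary of how concertedly the helices
move with the sheet.

## Functional mode analysis

The maximally correlated motion (MCM) is the unit-norm coefficient
vector `a` over the first *n* principal components maximizing the
Pearson correlation between `sum_k a_k p_k(t)` and a scalar functional
property `f(t)`. Maximizing Pearson correlation over a linear family is
solved in closed form by ordinary least squares on centered variables —
`fit_mcm()` does exactly that, then rescales to unit norm and orients
the vector so the building-set correlation is non-negative. A dense
search over coefficient directions on the unit sphere (an independent
oracle in the test suite) confirms the OLS direction to within 1° for
n ≤ 3.

Parameters and conventions:

* `essential_space_size(values, fraction = 0.90)` — *n* is the smallest
  number of leading PCs whose cumulative eigenvalue fraction reaches
  90%, the conventional essential-space size for this analysis.
* The **build/validation split defaults to 90%** of the frames (the
  45 ns / 5 ns convention at 50 ns): coefficients are fitted on the
  building window, `r_cv` evaluates the frozen model on the held-out
  tail. Both correlations are reported because a single quoted "FMA
  correlation" is ambiguous between them.
* `pc_contributions()` decomposes the modelled property variance as
  `%var_k = a_k² v_k / Σ_j a_j² v_j`. By default `v_k` is the
  **building-set projection variance** — the coefficients were fitted
  there, so this is the internally consistent weighting — but the
  full-trajectory eigenvalues can be passed instead and the switch is
  explicit in the API.
* Rank-deficient projection blocks (collinear PCs, possible with short
  windows) drop the dependent columns with a warning instead of
  returning an unstable solution.

## Water density maps and hydration scoring

`density_map()` bins water-oxygen positions on a rectangular grid of
0.5 Å spacing (the conventional resolution for hydration maps) covering
the solute plus a 10 Å margin, averages per-voxel counts over frames,
divides by the voxel volume, and normalizes by the bulk density
estimated in the 6–8 Å shell around the solute, with shell distance
measured to the nearest solute heavy atom. The shell mean of the
normalized map is therefore 1 *by construction*, which the tests assert
to 1e-12. An empty shell (too little padding, or no waters) is a hard
error: an unnormalizable map is meaningless. Nearest-voxel binning was
chosen over kernel density estimation as the most literal reading of
"number density at grid points"; it is exactly closed (summed counts ×
voxel volume equal the mean number of waters inside the grid), at the
cost of voxel-scale localization noise.

`hydration_sites()` returns voxels strictly greater than all (up to 26)
neighbours with `g > 1`, ordered by decreasing `g`. On maps estimated
from finitely many snapshots the bulk itself fluctuates, so the list
always contains shallow noise maxima with `g` marginally above 1 — this
is a property of the estimator, not a bug, and mirrors what real maps
look like. Workflows that need only genuine hotspots should read the
list from the top (planted-hotspot recovery in the tests uses the
top-ranked sites) or enable the optional 3×3×3 boxcar `smooth`.

`hydration_score()` aggregates sites around each atom as
`S_hyd(i) = Σ_s g_s · max(0, 1 − d_is/R_s)` with `R_s = 4 Å` by default.
The linear taper is a deliberately simple, testable weighting with the
two properties the score needs: it grows with nearby site density and
decays monotonically with distance, so atoms surrounded by many maxima,
or close to a few strong ones, score high and buried apolar atoms score
zero. The exact functional form of published atomic hydration scores
varies between implementations; this one is documented precisely so
results are interpretable, and the cutoff is configurable.

## Geometric features

**SASA.** `sasa()` is a Shrake–Rupley implementation with a
deterministic golden-spiral point set, 960 points per sphere and probe
radius 1.4 Å (water). Radii are Bondi by element (C 1.70, N 1.55,
O 1.52, S 1.80, H 1.20 Å), overridable. Heavy atoms only by default —
hydrogen placement differs between force fields and many structures lack
them — with `include_h = TRUE` available when hydrogens are trusted.
Determinism was preferred over random point sets so that areas are
bit-stable across runs; accuracy is checked against a 10⁶-point
Monte-Carlo oracle (2% on small clusters) and against the closed-form
isolated-atom value `4π(r+probe)²`, which is exact for this algorithm.

**Hydrogen bonds.** `hbonds()` enumerates donor–acceptor pairs passing
both a 3.5 Å acceptor–donor distance cutoff and a 30° acceptor–donor–
hydrogen angle cutoff. Donors are N/O atoms with a covalently attached
hydrogen (assigned within the same residue, < 1.25 Å); backbone amide
hydrogens may be inferred at ideal geometry — 1.01 Å along the bisector
of the N–CA and N–C(prev) directions — because their position is
essentially determined by the backbone, while side-chain donors require
explicit hydrogens (their rotameric ambiguity makes inference
unreliable). With inference disabled, a missing backbone hydrogen is a
hard error naming the donor. Acceptors are oxygens plus nitrogens
carrying no hydrogen. `hbond_series()` counts inter-group bonds per
frame in either donor/acceptor direction, the signal used to monitor
loop-contact formation along a trajectory.

**Secondary structure.** `assign_ss()` is a reduced four-state
classifier built on the classic electrostatic backbone H-bond energy
`E = 0.084·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)·332 kcal/mol` with bonds
at `E < −0.5`. Two consecutive i→i+4 bonds define helix (folding 3₁₀, α
and π into one H class), parallel/antiparallel ladder bridges define
strand, residues inside isolated 3/4/5-turns are T, everything else C.
Full eight-state assignment was deliberately out of scope: the
structural claims this package serves distinguish only
helix/strand/turn-or-coil transitions (e.g. a loop's turn-to-strand
conversion), and a reduced classifier is testable against canonical
geometries — an ideal poly-Ala helix labels H, an ideal antiparallel
pair labels E, a fully extended isolated chain labels neither. Residues
with missing backbone atoms are labelled C with a warning.

**Distance matrices.** `distance_matrix()` reports, per residue pair,
the window-averaged minimum distance over side-chain heavy atoms —
the quantity used to track hydrophobic-core packing over windows such as
the first and last 5 ns of a run. Glycine, which has no side-chain
heavy atom, contributes its Cα: a documented substitution that keeps
the matrix total and avoids NA rows.

Named residue sets from the PAH study (the hydrophobic surface patch,
the hydrophobic core, the L1–L4 loop regions, the ACT range 33–111) ship
as `named_residue_set()` in author numbering, which the package never
re-indexes.

## Sequence mapping

`global_align()` performs optimal global alignment with affine gaps
(BLOSUM62, gap open −10, gap extend −0.5) through
`Biostrings::pairwiseAlignment`; an independent score-only Gotoh dynamic
program in the test suite verifies the scores. For closely related
pairs — the human and rat PAH regulatory domains — identity is robust to
any reasonable parameter choice, which is why the defaults are ordinary
rather than tuned. `percent_identity()` divides identical pairs by
**aligned (non-gap) columns**; the denominator convention is fixed and
stated because quoted identity percentages depend on it. The package
reports identity over both the full regulatory domain (1–117) and the
ACT range (33–111), since either range can be meant when "the RD"
identity is quoted; on the bundled sequences they differ (≈84% vs ≈87%).

The FASTA shipped in `inst/extdata/pah_rd_sequences_synthetic.fasta` is
a *synthetic reconstruction* of the two regulatory-domain sequences
(UniProt accessions P00439 and P04176, residues 1–117), bundled so the
alignment stage is self-contained and reproducible offline; it is
labelled synthetic in both filename and headers, and should be replaced
with freshly fetched database sequences for any publication-grade use.

`atom_map()` converts an alignment into ordered pairs of equivalent
Cα atom indices — one per non-gap column whose residues both carry the
named atom — the input combined ED needs to pool homologous systems.

## The synthetic generators: what they emulate, and what they do not

The generators produce every input class the pipeline consumes, with
known population statistics, which is what turns the analysis stages
into testable code:

* `gen_chain()` builds ideal-geometry poly-Ala backbones (NeRF placement
  with standard bond lengths/angles) for canonical φ/ψ combinations;
  `"hairpin"` places two strands into a ladder-paired antiparallel
  arrangement by deterministic optimization of the rung H-bond
  distances, and `"mixed"` assembles a βαββαβ layout (four-stranded
  antiparallel sheet plus two helices) mimicking the ACT-domain fold
  topology for integration tests. The mixed layout is a spatial
  assembly of segments, not a folded chain: there are no connecting
  loops and no tertiary packing beyond the sheet.
* `gen_mode_trajectory()` draws frames
  `ref + Σ_k amp_k z_k(t) u_k + noise` with orthonormal planted modes
  (rigid-body components projected out, so no superposition step is
  needed before analysis) and i.i.d. standard-normal `z_k(t)`. The
  sample covariance converges to `Σ amp_k² u_k u_kᵀ + σ²I`, so ED must
  recover variance fractions `amp_k²/(Σ amp² + 3Nσ²)` — the recovery
  tests run at 79 residues and 5000 frames, the package's chosen
  study-scale configuration. Sampling is **memoryless by design**
  (an AR(1) option exists behind `rho`): the analyses this package
  implements are distributional, and reproducing kinetics or
  autocorrelation times is explicitly not attempted. Passing tests
  therefore validate the estimators, not the physics of any force
  field.
* `gen_coupled_property()` produces `f(t) = β·p(t) + ε` with known
  population correlation `r = β·sd(p)/sqrt(β²var(p)+σ²)`;
  `coupling_for_r()` inverts that formula so a channel can be planted at
  a chosen ground-truth correlation (the tests use 0.82, the headline
  FMA value of the motivating study, as a planted scenario — not as a
  reproduction of that study's trajectories, which are not deposited).
* `gen_solvated_frames()` scatters waters uniformly in a box (at least
  8 Å beyond the solute, so the bulk shell is always populated) with
  chosen fractions concentrated as Gaussian clouds on named atoms —
  planted hydration sites with analytically known expected density.
  Real water structure (layering, orientation, hydrogen-bond networks)
  is not modelled; only number-density statistics are.
* `gen_two_state_trajectory()` jitters around an open conformation
  before a planted switch frame and a closed one after it, so contact
  formation and SASA change have exact ground truth from the two
  endpoint structures.

Everything is bit-reproducible under a fixed seed, and generator
defaults are the package's fixed study conditions rather than knobs to
tune.

## Numerical conventions and degenerate inputs

* Coordinates are Å, times ps, energies kcal/mol; residue numbering is
  author numbering taken verbatim from the input.
* PDB output keeps 3 decimals (format precision); round-trips preserve
  coordinates to 0.001 Å and metadata exactly. Coordinates ≥ 10⁴ Å in
  magnitude cannot be represented and are refused. Alternate locations
  other than blank/'A' are dropped; insertion codes are rejected.
* Multi-model input must present identical atom sets per model; the
  first offending model is named in the error.
* Eigenvector and MCM sign conventions are as described above;
  correlation-web thresholds use strict inequality; the essential-space
  rule uses a 1e-12 slack so exact-fraction spectra do not flip on
  rounding.
* Zero-variance atoms (DCCM), single-frame trajectories (RMSF),
  all-zero spectra (essential space) and empty bulk shells each have a
  defined outcome — 0 with warning, 0 with warning, hard error, hard
  error — chosen so that silent NaN propagation cannot occur.

## Problem sizes

The validation suite runs entirely on synthetic systems sized to the
study it mirrors: 79 Cα atoms (the ACT domain length) with 5000 frames
for recovery of planted mode structure, a few thousand waters over tens
of snapshots for hydration maps, and hairpins/helices of 5–12 residues
for geometric fixtures. These sizes were chosen as the smallest at which
sampling error is comfortably below the tested tolerances (3 standard
errors for variance fractions, ±0.03 for planted correlations, one voxel
for hotspot localization).

## Known limitations

* The PDB reader handles the fixed-column subset needed for trajectory
  interchange; mmCIF, insertion codes and exotic records are out of
  scope, as is force-field/topology handling.
* The reduced secondary-structure classifier intentionally collapses
  DSSP's eight states to four and will disagree with full DSSP in
  boundary cases (helix termini, bulges, isolated bridges).
* The hydration score is a documented surrogate with the qualitative
  contract described above, not a re-implementation of any specific
  published scoring function.
* Binary trajectory formats (XTC/DCD) are not parsed natively; any
  converter producing multi-model PDB (or an adapter constructing
  `md_trajectory` objects directly from coordinate arrays) slots in at
  the `md_trajectory()` contract.
* The generators emulate distributions, not dynamics: no force field,
  no kinetics, no water structure beyond number density.
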