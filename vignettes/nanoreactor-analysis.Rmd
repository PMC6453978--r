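---
title: "Host-guest pairing, topochemical readiness and uptake analysis for nucleobase-lined porous crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-guest pairing, topochemical readiness and uptake analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoMOF)
```

## The system and the questions

An adeninate bio-MOF exposes the Watson-Crick (W-C) faces of its framework
adenines to one family of 1-D channels. Thymine guests absorbed from
solution can hydrogen-bond to those faces; two bound thymines whose C5=C6
double bonds are close and nearly parallel can photodimerize to the
cyclobutane thymine dimer under UV light. The package answers four
quantitative questions about such a host:

1. How much guest can the host hold? (void volume, density, capacity)
2. How often are guests W-C-locked to the walls, as a function of loading?
3. How often are guest pairs *topochemically ready* to dimerize?
4. How much guest actually entered the host in a solution experiment?

## Geometry kernel

Coordinates are Cartesian; the fractional frame uses the standard
lower-triangular cell matrix (a along x, b in the xy plane), so
`frac %*% cellMatrix(cell)` is the Cartesian position. Minimum-image
distances wrap the fractional displacement to the central image and then
search the +/-1 shell of lattice translations. This is exact whenever the
distances of interest are below half the shortest cell vector - true for
every criterion here (3.0 and 4.2 Angstrom cutoffs against cells of 8
Angstrom and up); the tests verify it against exhaustive image enumeration.

## Void volume and capacity

The probe-accessible fraction is computed on a grid over one unit cell
(origin fixed at the cell origin - no random offsets, so results are
deterministic). Two accessibility conventions exist in the literature and
both are implemented:

* **probe-center**: a point is accessible iff its distance to every atom is
  at least `r_vdw + r_probe`. This is the locus of probe centers.
* **contact-surface** (default): the free space after morphological opening
  of the van der Waals complement by the probe - every point within
  `r_probe` of an allowed probe center. This is the convention of the
  Mercury-style void calculation whose parameters (probe 1.2 Angstrom, grid
  ~0.7 Angstrom) are the defaults here, which is why it is the default
  mode.

The radius set is Bondi's, bundled and overridable: published void numbers
rarely state their radius table, so the table is a parameter rather than an
assertion. Grid error is controlled by the spacing; on an analytic sphere
the 0.7 Angstrom default is accurate to ~0.5% of cell volume and halving
the spacing tightens it (a tested property).

Capacity arithmetic is deliberately plain: per-formula-unit accessible
volume `V_FU = V_free/Z` (reported to 1 decimal), guest capacity
`V_FU / V_guest` (2 decimals, half away from zero - so 242.0/142.219 reads
1.70), and loading% x capacity for molecules per formula unit. Density is
`Z M_FU/(N_A V)` from standard atomic weights; gravimetric pore volume is
the algebraic `fraction/density`.

## Watson-Crick pairing metric

The A-T pair is operationalized as exactly two heavy-atom contacts,
`N1(Ade)-N3(Thy)` and `N6(Ade)-O4(Thy)`, both within an inclusive 3.0
Angstrom cutoff. Rationale for the choices:

* *Heavy atoms only*: the reference metrics are heavy-atom distances and
  hydrogens are frequently absent from host-guest models; no donor-H-angle
  criterion is applied by default.
* *Inclusive cutoff*: the DFT-optimized pair geometry has
  `d(N6-O4) = 3.00` Angstrom exactly; a strict cutoff would exclude the
  ideal geometry.
* *Matching*: each thymine is assigned to at most one adenine - the one
  with the smallest N1-N3 distance, ties broken by molecule id, making the
  event list deterministic.

The frequency statistic is the fraction of (frame, thymine) combinations in
a pairing event - the probability that a guest is locked at any instant.
Whether such a frequency should be normalized per guest, per frame or per
possible pair is convention; the per-guest form is the default and the
per-possible-pair form is always reported alongside
(`statisticPerPair`).

## Topochemical readiness

Two rules gate a candidate pair, both strict inequalities ("below 30
degrees", "< 4.2 Angstrom"):

* **Schmidt distance**: C5-C6 bond midpoint to C5'-C6' bond midpoint
  (minimum image) < 4.2 Angstrom. "Center-to-center" of two bonds is read
  as midpoint-to-midpoint; a closest-atom variant is available.
* **Alignment**: the folded line-line angle between the two bond vectors
  < 30 degrees. A 4-atom torsion is ill-defined for non-bonded fragments at
  general positions (the central "bond" is arbitrary), so the line-line
  angle is the default and the folded torsion is an option.

The folded angle maps parallel and antiparallel to 0: a C=C bond has no
head or tail for a [2+2] ring closure.

`predictDimerizationWindow()` encodes the mechanistic hypothesis that
photodimerization requires guests that are simultaneously *locked* (high
pairing frequency) and *ready* (high readiness frequency): it returns the
loadings where both profiles exceed their thresholds.

## The synthetic generator and what it does (not) emulate

`buildChannel()` builds a periodic channel along x with rigid, ideally
planar adenines (MMFF-optimized heavy-atom geometry) on alternating walls,
W-C faces pointing inward, two sites per 10.74 Angstrom period. The
default wall separation (8.2 Angstrom between the W-C edge lines) was
chosen by construction so that two guests locked at the two sites of one
period - the "two adenine units apart, opposite walls" motif - have C5-C6
midpoints ~3.4 Angstrom apart at ~0 degrees, inside both topochemical
thresholds with margin for thermal jitter, while all other locked-site
pairs are far outside them (> 12 Angstrom). This makes dimer-readiness a
plantable, testable property.

`simulateTrajectory()` draws each frame independently: every guest is
locked with probability `pPair` at a uniformly chosen free site (its two
contact distances drawn from Normal(2.85, 0.08) truncated to the near-ideal
2.7-3.0 Angstrom band - this truncated sampling *is* the thermal noise on
locked guests), otherwise placed uniformly in the channel interior with a
uniform random orientation plus Gaussian positional jitter (sd 0.25
Angstrom). Loadings convert to guest counts via the same 1.70
molecules-per-formula-unit capacity as the host arithmetic, one formula
unit per period.

The default locking schedule across the five-loading design
{25, 44, 56, 74, 100}% is {0.30, 0.75, 0.60, 0.50, 0.40}: locking peaks at
44% and deteriorates at higher loadings where dense packing disfavors
pairing, and is low at 25% where guests are sparse. Readiness then *emerges*
from random co-occupancy of motif site pairs - it is low at 25% (few locked
guests) and high from 44% up, so the joint pairing+readiness condition
singles out 44%.

What the generator does **not** emulate, and hence what passing tests do
not show about real systems: no force field or energies, no frame-to-frame
autocorrelation (real MD frames 2 ps apart are correlated; frequency
estimates here have binomial, not effective-sample-size, errors), no guest
flexibility, no competing solvent or cations, and no actual photochemistry.
It is a statistical stand-in whose planted parameters make every pipeline
statistic checkable, not a physical simulation.

All randomness flows from one integer seed through an isolated RNG stream
(the session's `.Random.seed` is never touched), and output is
bit-reproducible.

## Uptake quantification

Beer-Lambert conversion uses epsilon = 8217 1/(cm M) (thymine in
EtOH:MeCN at 263 nm) and a 1 cm path by default. Depletion experiments
reduce to `(c0 - c_final) V / (m / M_FU)` molecules per formula unit; the
default formula-unit mass is the desolvated host *including* the
charge-balancing dimethylammonium cation (the composition used for
elemental analysis), overridable. Negative depletion is flagged with a
warning, never clipped - an apparent negative uptake is a data problem the
caller should see. The solution volume is a required input: it is an
experimental choice that cannot be inferred.

Equilibration time is the first time point after which every subsequent
relative absorbance change stays below a tolerance (default 1%); a series
that never settles returns `NA` rather than a guess.

BET and Dubinin-Radushkevich fits are the standard linearizations
(`stats::lm` on the transformed coordinates). Because raw experimental
isotherms are not available here, these fits are validated purely on
forward-generated isotherms with known parameters: BET-generated data must
return its own parameters to fit precision, Langmuir data must be recovered
within 1% in the low-pressure regime where the two models coincide, and
D-R data must return the planted limiting uptake. A non-positive BET
constant flags the fit invalid.

## Numerical choices and degenerate inputs

* Grid spacing divides each cell edge into `ceiling(edge/spacing)` steps;
  a spacing larger than every edge is an error.
* Periodic atom images are generated one shell out, valid while inflated
  radii stay below the cell edges (asserted implicitly by the geometry of
  every supported case).
* Exactly coincident, equal-radius sites are merged in the Monte-Carlo
  surface-area sampler (two coincident atoms expose the area of one).
* Zero-length C5-C6 bond vectors, empty structures, changing trajectory
  cells, unknown element symbols, over-capacity guest requests and
  unsorted time series are all explicit errors naming the offending
  molecule, file or value.
* Trajectories assume a fixed cell (NVT-like); per-frame lattice headers
  that disagree are rejected.

## Problem sizes

The shipped tests run the full pipeline at deliberately modest sizes - 400
frames for the five-loading suite, 5000 frames for planted-probability
recovery (binomial SE ~0.008 at 3-4 guests), 1000 random frames for the
brute-force oracle comparisons - which already pin every statistic to its
planted value within tight sampling bounds. Larger runs only shrink error
bars that are not the limiting factor.

## Known limitations

* The CIF reader targets well-formed small-molecule CIFs (cell, symmetry
  operators, fractional coordinate loop); it is not a general CIF parser.
* Void fractions depend on the radius table and accessibility convention;
  comparisons across tools must fix both.
* The pairing metric is distance-only; it will count rare non-W-C contact
  geometries that happen to satisfy both distances.
* No Hoogsteen-face detection, no stereochemistry of the dimer product, no
  excited-state considerations: the screen is purely geometric.
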