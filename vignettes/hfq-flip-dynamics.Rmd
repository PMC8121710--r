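---
title: "Methods: syn/anti flip dynamics and interface fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syn/anti flip dynamics and interface fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system and the question

The hexameric bacterial chaperone Hfq binds ARN-repeat RNA (adenine /
purine / any-nucleotide triplets) on its distal face. In simulations of
such complexes the adenine of each repeat (the A position, "A_A") does not
sit still: it flips its base between the two rotamers of the glycosidic
torsion chi, *anti* (chi near 240 deg) and *syn* (chi near 60 deg), on the
nanosecond-to-microsecond timescale, while the surrounding interface
interactions -- hydrogen bonds into the A pocket, a single-water bridge to
the neighbouring purine, ion bridges to backbone carbonyls, van der Waals
packing of the N nucleotide against I30, and a guanine-specific type-4
base--phosphate (4BPh) contact that can pin the 3'-terminal G to the first
repeat's phosphate -- form and break in register with those flips.

`nucleoflip` implements the quantitative side of that analysis as a
reusable, tested package: chi computation and two-state classification,
debounced dwell statistics, geometric interaction detectors with occupancy
aggregation, state-conditioned distance histograms, coordinate-covariance
PCA, and the HBfix bias potential. Because microsecond-scale raw
trajectories of this system are not redistributable, the package also
contains a synthetic trajectory generator that emulates the *statistical*
structure of the dynamics with known ground truth, which is what the test
suite and the acceptance script run against.

## Two-state classification and debouncing

Chi is the dihedral O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
pyrimidines, computed with the standard signed atan2 construction and
wrapped to [0, 360). The atom quadruple follows the IUPAC convention; with
it, syn conformers fall near +60 deg and anti near 240 deg, which is
consistent with the classification windows below.

A frame is **syn** for chi in [-30, 150) and **anti** for chi in
[150, 330). The source ranges read as closed intervals, but a tie-break is
needed for the boundary values, so the windows are half-open on their
upper edge: exactly 150 deg is anti and exactly 330 deg (= -30 deg) is
syn. The two windows partition the circle, so every frame gets exactly one
label.

Counting every label change would be dominated by shoulder crossings, so
transitions are **debounced**: scanning left to right, an excursion to the
opposite state is accepted as a real transition only if it persists for at
least `min_dwell` (default 300 ps); shorter excursions are relabelled to
the currently accepted state. The semantics are deliberately asymmetric
(hysteresis, not symmetric smoothing): "short-lived new state is
rejected", which matches the idea of disregarding transitions that do not
last. Two boundary rules complete the definition:

* the initial run is always accepted (there is nothing before it to merge
  into), and
* the final run is accepted regardless of length and flagged *censored*,
  because its true duration is cut off by the end of the observation
  window.

Internally the scan is computed in closed form: raw runs strictly
alternate between the two states, so a run's debounced label is the state
of the last "anchor" run at or before it, where anchors are the initial
run, the final run, and every run of length at least `min_dwell`. The test
suite proves this equivalent to an independently written sequential scan
on ten thousand random sequences.

From the debounced labels, `transition_stats()` reports the number of
transitions, the syn population (fraction of frames), the time until the
first transition (absent -- printed as a dash -- when none occurred), and
the mean lifetime of each state. Two documented choices, both of which
were genuinely open:

* **Lifetimes use completed runs only** (runs terminated by a transition).
  The censored final run would bias the mean downward if included as-is
  and upward if extrapolated; "remained ... before flipping" describes
  completed dwells. Means that include the censored run are also reported
  (`mean_lifetime_*_censored_ns`) so the sensitivity is visible.
* **Populations are computed on the debounced labels**, consistent with
  counting debounced transitions; at default well widths the raw/debounced
  difference is far below the statistical noise of any realistic window.

## Interaction detectors

All detectors are purely geometric, per frame, and return a boolean
series; occupancy (fraction of frames, event count, mean event lifetime)
is aggregated by one shared routine. Distances use the minimum-image
convention when the trajectory carries an orthorhombic box.

| detector | criterion | default |
|---|---|---|
| H-bond | d(D,A) <= cutoff **and** angle(D-H-A) >= cutoff | 3.5 A, 120 deg |
| water bridge | one water O satisfies the H-bond criterion with both partners simultaneously | 3.5 A |
| ion bridge | one ion within cutoff of both partners | 3.5 A |
| 4BPh | guanine N1-H1 *and* N2-H2 both H-bond to OP1/OP2 of one phosphate | as H-bond |
| vdW contact | minimum heavy-atom pair distance <= cutoff | 4.5 A |

Both H-bond boundaries are closed (a pair at exactly 3.5 A / 120 deg
counts as bonded). Without hydrogens the H-bond detector runs in a flagged
distance-only mode rather than failing -- many deposited structures and
all packaged fixtures lack hydrogens -- and the water-bridge angle test is
applied only when water hydrogens exist. The distance-only fallback is
never silent: requesting a specific hydrogen that does not exist is an
error.

The 4BPh detector is guanine-specific by construction (it refuses other
residues), and strict by default: both donors must engage the same
phosphate, the defining geometry of the type-4 class, with a lenient
single-donor mode behind a flag. The ion-bridge (3.5 A) and vdW (4.5 A)
cutoffs are conventional values -- the source analyses state none -- and
are exposed in the configuration.

State-conditioned histograms (the K31(O)-A_A(O4') observable) bin
per-frame distances at 0.1 A and normalise each state's histogram to unit
*sum* rather than unit area; "normalized" does not specify which, and unit
sum keeps masses comparable across bin widths. A plotted "average
distance" could also mean histogramming per-simulation averages; this
implementation histograms per-frame distances, which preserves the
within-state spread. States with zero frames are omitted, not zero-filled.
The close-contact observable itself is only measured and histogrammed;
no attempt is made to classify it as "repulsive".

## Collective motion

`superpose()` removes rigid-body motion by unweighted least squares
(Kabsch, via the SVD) on a user selection -- at least three non-collinear
atoms -- against either the first frame or an iteratively refined mean
structure (refit until the mean moves < 1e-6 A RMSD). `traj_pca()` then
builds the covariance of the mean-centred Cartesian coordinates using
every fifth frame (configurable), diagonalises it, and keeps the first ten
eigenvectors by default; projections are reported for *all* frames, not
only the strided ones. The covariance is not mass-weighted (the source
does not state a weighting, and the fixture contracts define unweighted
behaviour), and the default fit selection is the heavy-atom backbone.
Eigenvector signs are fixed by making the largest-magnitude loading
positive, so output is deterministic. Eigenvalues are reported as
computed; the spectrum of a symmetric eigendecomposition can carry
negatives at the 1e-15 level, which the invariants tolerate explicitly.

## The HBfix bias

HBfix stabilises a named native H-bond by a constant eta within the
bonding distance and ramps linearly to zero over a short window:

U(r) = -eta for r <= r_full; -eta (r_off - r)/(r_off - r_full) for
r_full < r < r_off; 0 beyond r_off.

Defaults are eta = 1 kcal/mol (the "mild" setting; 2 kcal/mol is the
stronger control variant, and linearity in eta makes it an exact doubling)
with the window [3.0, 4.0] A on the donor-acceptor heavy-atom distance.
The window follows the published HBfix convention; the exact values the
original simulations used live in supplementary material outside this
package's sources, so they are flagged as conventional defaults, not a
reproduction. The potential is C0 only; the radial force -dU/dr is
reported with the ramp-side value at the two kinks, documented rather than
smoothed. Evaluation and restraint export are the entire scope -- nothing
feeds back into an MD engine.

## What the synthetic generator emulates -- and what it does not

Each nucleotide's flip process is an alternating renewal process:
independent dwells drawn per state (exponential by default, memoryless
like a barrier-crossing process; a fixed-duration mode exists for
exact-count tests), decorated with *blips* -- excursions of 100-200 ps,
below the debounce threshold -- at a configurable rate, mimicking the fast
shoulder crossings the debouncer must reject. Chi values are drawn from
Gaussian wells at 60/240 deg with a 15 deg width, placing the window edges
about six standard deviations away so label recovery exceeds 99.9%.

One design point deserves emphasis: **dwells are floored at the debounce
threshold** (300 ps, configurable). A true dwell shorter than the
threshold is observationally indistinguishable from a blip, and a
generator that emitted such dwells could not be recovered exactly by any
debouncing analysis; sub-threshold excursions therefore exist only in the
explicit blip channel, and the ledger's transition count is exactly the
quantity the pipeline should recover. For exponential dwells the floor
shifts the realised mean to (mean + floor) by memorylessness -- e.g.
nominal 2/8 ns dwells realise 2.3/8.3 ns with a stationary syn fraction of
2.3/10.6 ~ 0.217 -- and the ledger records the realised values, which is
what recovery is measured against.

The coordinate realiser builds a minimal scene per repeat -- a ribose +
phosphate + purine nucleotide whose base is rotated rigidly about the
glycosidic bond so the recomputed chi matches the schedule exactly, plus
partner pseudo-atoms placed to satisfy or violate each scheduled
interaction frame by frame. Scheduled-off partners are displaced ~10 A
rather than deleted, keeping the atom list constant. The packaged
geometry fixture carries seven N-pocket sites (six engaged, one flipped
away) so both occupancy regimes are represented.

What passing tests on this data do **not** show: the generator has no
physics. Frames are independent snapshots (no inertia, no autocorrelation
within a dwell), solvent is a single schedulable water per bridge, there
are no force-field energies, repeats flip independently (whether real
flips synchronise across repeats is an open question; a coupling parameter
exists for exploration only), and dwell distributions in real trajectories
need not be exponential. The tests validate the *bookkeeping and
geometry* of the analysis exactly, and its statistical estimators under a
known model -- they cannot validate force fields or sampling.

## Problem sizes and reproducibility

The dwell-statistics conditions are six repeats observed for 5 us at a
10 ps frame interval (500,000 frames per repeat), the acceptance script's
default; the bundled analysis scripts use a 1 us window for quick
turnaround, and unit tests use shorter windows still, since the
bookkeeping properties they check are size-independent. Coordinate
fixtures are tens of frames: the detectors are per-frame, so length adds
nothing but runtime. Every stochastic step takes a seed, and
`run_pipeline()` writes a manifest with md5 checksums of every output;
two runs from one seed are byte-identical (the package's determinism
contract, enforced by the test suite).

## Known limitations

* Only two conformational states; no multi-well or Markov-model analysis
  beyond empirical dwell means.
* PDB is the interchange format; binary trajectory formats would need an
  adapter behind the same `trajectory()` contract.
* The selection grammar covers conjunctions, lists and ranges of
  chain/residue/name/element, not distance-based or within-style
  selections.
* No stacking classifier, no energetics, no per-residue RMSF; the HBfix
  module evaluates but does not simulate.
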