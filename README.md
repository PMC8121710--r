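# nucleoflip

Analysis toolkit for molecular-dynamics trajectories of protein–RNA
complexes, built around a system where the RNA does something unusual: on
the distal face of the bacterial chaperone Hfq, the adenine of each bound
ARN repeat flips its base between the *anti* and *syn* rotamers of the
glycosidic torsion χ on nanosecond-to-microsecond timescales, and the
interface chemistry — A-pocket hydrogen bonds, a single-water bridge to
the neighbouring purine, backbone ion bridges, I30 van der Waals packing,
and a guanine-specific type-4 base–phosphate (4BPh) contact — switches in
register with those flips.

The package provides, as tested building blocks:

* **Conformer dynamics** — χ torsions (O4′–C1′–N9–C4 / O4′–C1′–N1–C2);
  syn/anti classification with windows χ ∈ [−30°, 150°) → syn,
  [150°, 330°) → anti; *debouncing* that disregards excursions shorter
  than 300 ps before counting transitions; dwell statistics (transition
  counts, syn populations, time to first transition, mean state lifetimes
  over completed runs, with censored-run bookkeeping).
* **Interaction fingerprints** — per-frame H-bond detection
  (d(D,A) ≤ 3.5 Å and ∠D–H–A ≥ 120°), water/ion bridges, strict
  two-donor 4BPh detection, minimum-distance vdW contacts (≤ 4.5 Å),
  occupancy aggregation, and state-conditioned distance histograms.
* **Collective motion** — least-squares superposition (Kabsch) and
  coordinate-covariance PCA using every fifth frame and the first ten
  eigenvectors by default, with projections for all frames.
* **HBfix** — the flat-ramp H-bond stabilisation
  U(r) = −η for r ≤ r_full, linear to 0 at r_off (defaults η = 1 kcal/mol,
  window [3.0, 4.0] Å), its radial force, per-trajectory bias profiles and
  restraint export.
* **Synthetic data** — a ground-truth-labelled generator (alternating-
  renewal dwell processes with sub-threshold "blips", χ wells at 60°/240°,
  schedulable interface geometries realised as multi-model PDB) so the
  entire pipeline is testable without microsecond raw trajectories, which
  are not redistributable for this system.

Multi-model PDB is the interchange format (read/write via bio3d behind the
package's `topology()`/`trajectory()` containers), with a small selection
grammar (`"chain R and resid 1,4,7 and name C1'"`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic suite (`Rscript analysis/01_simulate.R` … `05_hbfix.R`), writing
tables under `results/`. The core of stage 2, by hand:

```r
library(nucleoflip)

suite <- make_fixture_suite("fixtures", seed = 1, total_ns = 1000)
chi <- read.csv("fixtures/dwell_fixture_chi.csv", check.names = FALSE)
rep_df <- dwell_report(lapply(chi, angle_series, dt = 10), min_dwell = 300)
format_dwell_report(rep_df)
```

prints the classic three-row presentation, one column per repeat:

```
I: transitions/syn population     5/0.97 7/0.57 8/0.18 6/0.37  12/0.22 8/0.33
II: time to first transition (ns) 15     111    148    68      230     125
III: mean lifetimes syn/anti (ns) 198/9  72/108 44/197 124/183 36/109  84/114
```

Row I counts debounced syn/anti transitions and the syn fraction; row II
is the simulation time of the first flip (a dash when none occurred); row
III averages each state's dwell over completed runs. Here the counts match
the generator's ledger exactly — e.g. repeat A1 was scheduled with long
syn dwells (300 ns) and short anti dwells (20 ns), and is recovered as
syn-dominant (0.97) with 5 flips. On the blip-rich fixture the same
classification gives 32 raw transitions, of which debouncing at 300 ps
keeps the 6 scheduled real ones.

Stage 3 reports interface occupancies on the coordinate fixture — the six
engaged N-pocket sites show I30 contact occupancy 1.0 and the flipped-away
site 0.0 — and the state-conditioned K31(O)–A1(O4′) histogram puts the
modal distance at 2.95 Å in anti versus 4.05 Å in syn: the base flip
relieves the close backbone contact.

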