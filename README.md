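# mitodyn

Simulation and quantification of mitochondrial network dynamics in live
skeletal muscle, as measured by the photoactivatable-fluorescent-protein
migration assay.

## The problem

Skeletal-muscle mitochondria form networks aligned with the sarcomere
lattice, continuously remodeled by fission and fusion. Photoactivating a
mitochondria-targeted fluorescent protein (mt-PAGFP or a Dendra2 fusion) in a
~10 x 10 um^2 region of a live fiber and imaging the activated species
together with TMRE (a membrane-potential dye) turns content exchange into a
measurable front: migration is scored in **m-steps** (one average sarcomere
length, 2.2 um) and follows a two-phase time course,

* `rate_early` — zero-intercept regression over the first 2 min
  (diffusion within already-connected mitochondria, dashed line),
* `rate_late` — free-intercept OLS slope after 2 min
  (fission/fusion-limited remodeling, solid line),

with group statistics reported as mean ± SEM of m-steps migrated over the
18-min window after the first frame, compared by Student's t test. In an
ALS model (SOD1^G93A), migration slows in both phases, mutant SOD1 forms
aggregates inside mitochondria colocated with local TMRE loss, the network
fragments, partial depolarization by FCCP mimics the defect, and the Drp1
(fission) inhibitor Mdivi-1 restores migration.

`mitodyn` provides, as five modules behind one package:

* `netsim` — a stochastic lattice model of the fiber (exact event-driven
  fission/fusion + deterministic tracer mixing in compiled code) with
  confocal-like two-channel rendering and per-condition presets
  (`control`, `g93a`, `mtSOD1`, `mtSOD1G93A`, `fccp`, `mdivi1`), each
  carrying ground truth;
* `quantify` — background estimation, directional band profiles, threshold
  fronts, migration curves in m-steps;
* `rates` — the two-phase fit, published-style rate ratios, cohort
  summaries;
* `morphology` — TMRE segmentation, fragmentation classification, aggregate
  detection, per-aggregate depolarization scores;
* `cli_io` — text image-series format with JSON sidecar, CSV tables, and a
  CLI (`simulate`, `quantify`, `fit`, `morphology`, `report`).

## Worked example

```r
library(mitodyn)

sm <- simulate_experiment("control", seed = 1)  # two-channel series + truth
cv <- migration_curve(sm)                        # m-steps vs time
fit_two_phase(cv)
```

```
<migration_curve> m-steps (mean of long+, long- )
   time_min  steps
1         2  7.167
2         4  7.189
...
10       20 12.678
<two_phase_fit> early 3.584 m-steps/min (dashed), late 0.375 m-steps/min (solid), 18-min total 5.51
```

This fiber's tracer reached 7.2 m-steps within the first 2 min (early rate
3.58 m-steps/min — fast spread through the pre-connected network), then
advanced another ~5.5 m-steps over the remaining 18 min (late rate
0.375 m-steps/min — fusion-limited). Cohort means over 20 control fibers
recover the calibrated 3.7 / 0.47 m-steps/min. The published ratio
arithmetic is exact:

```r
rate_ratio(0.47, 0.13)   # 3.6  — control / G93A, after 2 min
rate_ratio(3.70, 2.25)   # 1.6  — control / G93A, first 2 min
```

Morphology on a mutant-SOD1 fiber:

```r
morphology_report(simulate_experiment("mtSOD1G93A", seed = 1, frame_times = 2))
```

```
<morphology_report> mtSOD1G93A_s1: 174 components, median length 8.2 um, fragmented=TRUE, 7 aggregates
```

— a fragmented network (typical fragment 8.2 um < 20 um cutoff) with 7
aggregate puncta whose TMRE dips are scored individually.

End-to-end cohorts, from the shell:

```sh
Rscript -e 'mitodyn::mito_cli()' report --out report/ --seed 1 --nfibers 12
Rscript -e 'mitodyn::mito_cli()' simulate --preset control --seed 7 --out series/ --frames 2:20:2
Rscript -e 'mitodyn::mito_cli()' quantify --in series/ --threshold 0.10 --out curve.csv
```

`report` writes per-fiber curve CSVs, a published-table-shaped rate table
with ratio columns against the reference condition, morphology and
aggregate CSVs, and a log; every file regenerates bit-identically from the
same seed.

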