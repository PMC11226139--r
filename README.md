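# lqt8sim

Computational study of ventricular arrhythmogenesis in Long QT syndrome
type 8 (Timothy syndrome). The G406R mutation of the CaV1.2 L-type calcium
channel impairs voltage-dependent inactivation, prolongs the action
potential, and — when it meets the intrinsic transmural heterogeneity of
the ventricular wall — amplifies the dispersion of repolarization that lets
premature beats block intramurally and trigger reentrant tachycardia.
`lqt8sim` is an R package for cardiac electrophysiologists and modellers
who want to simulate that chain of mechanisms end to end on a desk machine
and at scale.

## What it implements

* **Membrane kinetics** — the ten Tusscher–Panfilov 2006 (TP06) human
  ventricular model with a mixed L-type calcium current
  `ICaL = (1 − ρ) ICaL_WT + ρ ICaL_TS`, where ρ is the G406R heterozygosis
  fraction (0.11 and 0.5 for the TS-11% / TS-50% genotypes). Each variant
  has its own activation and voltage-inactivation gates; the mutant
  activates earlier (d-gate midpoint −8 vs −4 mV) and inactivates far less
  at plateau potentials (f-gate midpoint 0 vs −20 mV, slope 12 vs 7).
  Transmural ENDO/MID/EPI phenotypes differ by an IKs scaling factor
  (HET1: 1.3/0.5/1.4, mid-wall M cells longest; HET2: 0.7/1.1/1.4,
  sub-endocardium longest; HOM: uniform 1.3).
* **Tissue** — the Bidomain equations (and their monodomain harmonic-mean
  reduction) with transversely isotropic conductivity tensors, discretised
  by Q1 hexahedral finite elements and a semi-implicit double operator
  splitting (Rush–Larsen gates at frozen potential, elliptic extracellular
  solve, implicit parabolic step; conjugate-gradient solvers). Geometries:
  1D cables, Cartesian slabs, and the idealized truncated-ellipsoid left
  ventricle (6,447,616 nodes at the reference 512 x 256 x 48 resolution)
  with 120-degree rule-based transmural fiber rotation.
* **Programmed ventricular stimulation** — 8 S1 beats at BCL 500 ms, then
  S2/S3/S4 extrastimuli with 10-ms coupling decrements, checkpointed and
  deterministic, with capture, intramural conduction-block and
  sustained/nonsustained reentry classification.
* **Post-processing** — activation (max-slope), repolarization (min-slope,
  EAD-aware) and APD markers on a 64 x 33 x 7 transmural needle-electrode
  array (14,784 sites), and the five dispersion statistics `dAT_tot`,
  `dRT_tot`, `dRT_trans`, `dAPD_tot`, `dAPD_trans`.
* **Synthetic fixtures** — analytic AP templates and seeded marker fields
  with closed-form truths, used by the test suite as oracles.

See `vignettes/lqt8sim-methods.Rmd` for the model equations, parameter
choices, numerical design decisions and known limitations.

## Worked example

Pace a 2-cm single-phenotype cable (h = 0.02 cm, conductivity 2 mS/cm) of
TS-11% midmyocardial cells in the HET1 setting for eight beats at
BCL = 1000 ms and measure the last action potential at mid-cable:

```r
library(lqt8sim)

cable <- build_cable(n_elems = 100, h = 0.02, sigma = 2)
trace <- run_cable_pacing(cable, mutation_setting(rho = 0.11),
                          iks_factor = iks_factor_for("MID", "HET1"),
                          bcl = 1000, n_beats = 8)
trace
#> Paced cell trace: 8 beat(s) at BCL 1000 ms
#>   last beat: ACTI 11.0 ms, REPO 366.0 ms, APD 355.0 ms
```

The activation marker (ACTI) is the instant of steepest depolarization at
the recording site, the repolarization marker (REPO) the instant of
steepest final repolarization; their difference is the action potential
duration — here 355 ms, a 14-ms prolongation over the wild-type value of
the same phenotype (341 ms), reflecting the 11% mutant channel fraction.
`run_table1()` produces the full 18-row phenotype-by-genotype APD report
with deltas against the study's reference values.

Dispersion statistics work the same way on simulated tissue or on
synthetic marker fields:

```r
mf <- make_marker_field(64, 33, 7, acti_range = 120, trans_range = 45,
                        profile = "midwall", noise_sd = 6, seed = 1)
dispersion_summary(mf$markers)
#> Dispersion of activation/repolarization (ms):
#>   dAT_tot    143.0
#>   dRT_tot    190.6
#>   dRT_trans   50.2 +/- 7.0
#>   dAPD_tot   111.4
#>   dAPD_trans  53.6 +/- 9.4
```

For tissue runs, build a mesh (`build_ellipsoid_mesh()`,
`build_slab_mesh()`), a `tissue_problem()`, and drive it with `advance()`
or the full protocol via `run_pvs()`; fields export to legacy VTK with
`write_vtk_mesh()`. A thin command-line wrapper over these functions is
installed at `inst/scripts/lqt8sim-cli.R`.

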