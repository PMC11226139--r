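---
title: "Modelling LQT8/Timothy-syndrome arrhythmogenesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LQT8/Timothy-syndrome arrhythmogenesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Long QT syndrome type 8 (Timothy syndrome) arises from mutations of the
CACNA1C gene encoding the CaV1.2 subunit of the L-type calcium channel. The
G406R mutation impairs voltage-dependent inactivation (VDI) of the channel,
prolonging the inward calcium current, the action potential and the QT
interval, and predisposing to reentrant ventricular tachycardia. Because the
ventricular wall is electrically heterogeneous — midmyocardial (M) cells or
sub-endocardial cells may carry intrinsically longer action potentials than
their neighbours — the mutation amplifies *transmural dispersion of
repolarization*, the classical substrate for unidirectional conduction block
of premature beats and reentry.

`lqt8sim` implements the full simulation chain needed to study this
mechanism:

1. a human ventricular membrane model (ten Tusscher–Panfilov 2006, TP06)
   with a wild-type/mutant ICaL mixture and layer-dependent IKs scaling;
2. a Bidomain reaction–diffusion tissue model (with monodomain reduction)
   discretised by Q1 hexahedral finite elements on cables, slabs and an
   idealized truncated-ellipsoid left ventricle with rule-based fibers;
3. an S1–S2–S3–S4 programmed ventricular stimulation (PVS) engine with
   capture, conduction-block and reentry classification;
4. post-processing of activation (ACTI), repolarization (REPO) and APD
   markers on a 64 x 33 x 7 transmural needle-electrode array, with five
   dispersion statistics.

## Membrane model

The base kinetics are TP06 (19 state variables). The mixed L-type calcium
current is

$$ I_{CaL} = (1-\rho)\, I_{CaL}^{WT} + \rho\, I_{CaL}^{TS}, $$

where $\rho$ is the heterozygosis fraction: $\rho = 0.11$ for the TS-11%
genotype (mutant exon-8A protein only) and $\rho = 0.5$ for TS-50% (mutant
exon-8 and exon-8A protein). Each variant carries its own activation gate
$d_*$ and voltage-inactivation gate $f_*$ (the package state therefore has
21 variables); the slow VDI gate $f_2$, the calcium-dependent gate
$f_{Cass}$, the GHK-type driving term and the maximal conductance $g_{CaL}$
are shared. Steady-state curves are

$$ d_\infty^*(V) = \frac{1}{1 + e^{(V_{a05}^* - V)/S_a^*}}, \qquad
   f_\infty^*(V) = \frac{1}{1 + e^{(V - V_{ina05}^*)/S_{ina}^*}}, $$

with (WT) $V_{a05} = -4$ mV, $S_a = 7.5$, $V_{ina05} = -20$ mV,
$S_{ina} = 7$, and (TS/G406R) $V_{a05} = -8$ mV, $S_a = 7.5$,
$V_{ina05} = 0$ mV, $S_{ina} = 12$: the mutant activates earlier and
inactivates much less at plateau potentials. Mutant gates use the unchanged
TP06 time constants — the mutation is modelled purely through the
steady-state curves. Note that the WT calibration is itself a recalibration
of TP06 (stock TP06 has $d_\infty$ midpoint $-8$ mV, available as
`gate_params_tp06()`); with stock gates and $\rho = 0$ the model degenerates
exactly to unmodified TP06.

Transmural heterogeneity enters only through a multiplicative factor on the
IKs conductance:

| setting | ENDO | MID | EPI | longest AP |
|---------|------|-----|-----|------------|
| HET1    | 1.3  | 0.5 | 1.4 | midmyocardial (M cells) |
| HET2    | 0.7  | 1.1 | 1.4 | sub-endocardial |
| HOM     | 1.3  | 1.3 | 1.3 | (uniform, ENDO calibration) |

All layers share a single TP06 base formulation. We use the epicardial
variant: the published APD table is internally consistent with a single base
(the factor-1.4 EPI column repeats identical APDs in both HET settings), and
among the three TP06 variants only the epicardial base reproduces the
wild-type rows (the M-cell base, whose IKs conductance is already four times
smaller, overshoots the mid-wall values by over 25%). The base is
configurable (`base_cell_type`).

### A documented model extension: incomplete mutant VDI

With the parameter values above, the package reproduces the study's
reference APD table (BCL 1000 ms, single-phenotype cables) to within about
3% for all wild-type and TS-11% phenotypes, but *underestimates every
TS-50% value* (by about 7% in the short-APD layers and 24–27% in the two
EAD-bearing phenotypes, which show no EADs here). Experimentally, G406R
does not merely shift VDI — it leaves a large fraction of mutant channels
non-inactivating (the inactivation curve has a pedestal). The optional
`ts_floor` parameter of `gate_params()` models this:

$$ f_\infty^{TS}(V) = (1-\phi)\,\frac{1}{1 + e^{(V - V_{ina05})/S_{ina}}}
   + \phi. $$

With $\phi = 0.2$ the reference table is reproduced to about 2% in 16 of 18
entries (the two EAD phenotypes remain long only when EADs actually fire).
The package default is $\phi = 0$ — the plain printed sigmoid — and every
reported number in the tests and the acceptance script uses the default;
`ts_floor` is provided as a clearly-labelled extension for users who want
the stronger, experimentally-motivated mutant phenotype.

### Integration of the membrane ODEs

Gates are advanced by Rush–Larsen exponential updates with the membrane
potential frozen at $v^n$ (this is the ODE half of the operator splitting);
concentrations by a forward step with instantaneous-buffer correction
(quadratic solve); and the ionic current for the potential update is
re-evaluated at $(v^n, w^{n+1}, c^{n+1})$. The ryanodine-receptor adaptation
variable, linear in itself for frozen subspace calcium, also uses the
exponential update. At $\tau = 0.05$ ms, halving the step changes a cable
APD by well under 1 ms (verified in the tests).

## Tissue model

The Bidomain system couples the transmembrane potential $v$ and the
extracellular potential $u_e$:

$$ c_m \partial_t v - \nabla\!\cdot\!(D_i \nabla (v + u_e)) + i_{ion} = i_{app},
 \qquad -\nabla\!\cdot\!((D_i + D_e)\nabla u_e) = \nabla\!\cdot\!(D_i \nabla v), $$

with insulated (zero-flux) boundaries and transversely isotropic tensors
$D = \sigma_t I + (\sigma_l - \sigma_t)\, a_l a_l^T$ along the local fiber
$a_l$. Conductivities are $\sigma_l^e = 2$, $\sigma_l^i = 3$,
$\sigma_t^e = 1.3514$, $\sigma_t^i = 0.31525$; these are printed in mS and
interpreted here as mS/cm, the only reading under which the equations are
dimensionally consistent. The volumetric capacitance is not printed; we use
$c_m = 1$ mF/cm^3 (surface-to-volume ratio 1000 /cm at 1 uF/cm^2), exposed
in `solver_config()`. With these choices the monodomain longitudinal
diffusivity is $1.2\times10^{-3}$ cm^2/ms and a paced cable conducts at
about 0.06 cm/ms, in the physiological range.

Space is discretised with isoparametric Q1 hexahedra (consistent mass
matrix; a lumped vector is also assembled and used as the weights of the
zero-mean gauge). Time uses the double operator splitting: (1) membrane ODE
stage at frozen $v^n$; (2) elliptic solve for $u_e^n$; (3) semi-implicit
parabolic solve for $v^{n+1}$, with $i_{ion}$ evaluated at
$(v^n, w^{n+1}, c^{n+1})$. Both linear systems use Jacobi-preconditioned
conjugate gradients with warm starts (relative residual $10^{-10}$
parabolic, $10^{-8}$ elliptic, plus an absolute floor of $10^{-12}$ for
quiescent states whose right-hand side is zero to roundoff). The elliptic
operator is singular with the constants as null space: the residual is kept
consistent by unweighted mean removal, and the solution gauge is fixed to
zero mass-weighted mean. The monodomain reduction uses the harmonic-mean
tensor $D_m = D_i (D_i + D_e)^{-1} D_e$, which for coaxial transversely
isotropic media is the per-eigenvalue harmonic mean; under proportional
tensors ($D_e = \lambda D_i$) the two models agree to the splitting error
(under 0.5 mV on the test slab), and the elliptic stage satisfies
$u_e = -v/(1+\lambda)$ exactly up to solver tolerance.

The 1D cable uses the same splitting with a precomputed tridiagonal
(Thomas) solve and mirrored-ghost Neumann ends; with a single node and zero
diffusivity it reproduces the space-clamped cell stepping bit for bit,
which the tests assert.

## Geometry

The idealized left ventricle is the image of a periodic Cartesian slab
under truncated-ellipsoid coordinates with semi-axes 1.5/2.7 cm
(endo/epi, equatorial) and 4.4/5 cm (apex-base), $\phi$ spanning a full
period (the circumferential seam is closed by node identification) and
$\theta \in [-3\pi/8, \pi/8]$. At the study resolution of
512 x 256 x 48 elements the mesh has exactly 6,447,616 nodes. Fibers rotate
linearly with depth, counterclockwise from epicardium to endocardium, by a
total of 120 degrees; the angle is measured from the circumferential
direction in the local tangent frame (circumferential and meridional
coordinate tangents, Gram–Schmidt orthonormalised), with the epicardial
angle at -60 degrees so the rotation is symmetric about mid-wall. The wall
is split into ENDO/MID/EPI layers of equal depth; nodes exactly on a
boundary belong to the layer toward the endocardium. All of these
conventions are arguments with the stated defaults.

## Stimulation protocol

The PVS plan follows the clinical S1–S4 protocol: 8 S1 stimuli at a basic
cycle length of 500 ms (350 mA/cm^3 for 1 ms on a 0.12 x 0.12 x 0.06 cm^3
footprint; endocardial site for HOM/HET1, epicardial for HET2, centred
between apex and base), then S2 from 380 ms coupling, S3 and S4 from 350 ms
after the previously accepted extrastimulus, each decremented by 10 ms
until an arrhythmia is induced or capture is lost; each accepted coupling
is frozen before the next level is searched (the protocol text implies but
does not state this; we record it as our reading). Every attempt restarts
from a checkpoint of the state at the previous stimulus, so searches are
deterministic and reproducible. The classification window is 4000 ms after
the last stimulus.

Three detectors operationalise qualitative statements in the protocol:

* **capture** — a new upstroke (crossing -20 mV with dV/dt > 10 mV/ms) in a
  ring just outside the stimulus footprint within 50 ms;
* **intramural conduction block** — the wavefront propagates at least
  0.3 cm beyond the footprint (cables) or into the mid-wall layer (3D) but
  never reaches the opposite surface within 150 ms; this deliberately
  excludes marginal capture-limit failures, which die within about 0.2 cm
  of the stimulus in homogeneous media;
* **re-activation** — an upstroke later than 300 ms after the stimulus;
  reentry is *sustained* if re-activations persist into the final 500 ms of
  the observation window, *nonsustained* otherwise.

All thresholds are `pvs_plan()` arguments.

## Post-processing

ACTI is the instant of maximal dV/dt during depolarization and REPO the
instant of minimal dV/dt during final repolarization, both by central
differences on the stored 1-ms sampling grid; APD = REPO - ACTI. For
EAD-bearing traces the REPO search window opens after the last local
voltage maximum above -40 mV, so the marker lands on terminal
repolarization rather than on the EAD downslope (the study defines the
marker only as "minimal slope during repolarization"; the post-hump window
is our reading, and it is exercised against analytic two-hump templates).
Traces that never cross -20 mV, or that do not return below -70 mV, yield
missing markers; missing markers are excluded from aggregation with a
reported count. The five dispersion statistics over the 64 x 33 x 7 needle
array are plain max-min ranges (totals) and per-needle range means with SD
(transmural), verified against exhaustive brute force.

Needle placement on the ellipsoid is 64 equispaced circumferential
positions, 33 equispaced apex-base positions and 7 transmural sites
including both surfaces (site 1 epicardial) — the study says only "equally
distributed", so the layout is configurable.

## Synthetic fixtures

`ap_template()`/`make_ap_trace()` build analytic action potentials from
sigmoidal rise and fall (optionally with a Gaussian EAD hump) whose
steepest-slope instants — the marker truths — are the sigmoid centres.
`make_marker_field()` generates seeded marker fields with a planar
activation gradient and a configurable transmural repolarization profile
(`linear`, `midwall` emulating HET1-like mid-wall prolongation, `endo`
emulating HET2-like sub-endocardial prolongation) plus Gaussian noise; the
exact dispersion truths of each realised field are computed by exhaustive
aggregation at generation time and stored alongside. These fixtures emulate
the statistical structure of the tissue maps (gradients, noise, layout) but
not wave propagation, electrotonic smoothing or reentry dynamics — passing
marker/dispersion tests therefore validates the post-processing chain, not
the solver, which has its own oracle tests.

## Problem sizes and what the test suite does (and does not) show

The packaged tests run, on one CPU in a few minutes: the 18-combination APD
table on 2-cm single-phenotype cables (h = 0.02 cm, tau = 0.05 ms, 8 beats
at BCL 1000 ms); full-resolution mesh construction with geometric
invariants (node count, Jacobian positivity, surface residuals); FEM
assembly and solver oracles on small slabs; and S2-only decrement searches
on 1.2-cm transmural ENDO|MID|EPI cables (2 S1 beats at BCL 500 ms, 500-ms
attempt windows). Full-resolution FEM assembly and the complete S1–S4
protocol on the 3D ventricle at wave-resolving resolution are
cluster-scale computations; the package supports building and running them
(`tissue_problem()` on an ellipsoid `lqt8_mesh`, `run_pvs()`), but the
suite does not execute them, so the published 3D dispersion values and the
reentry outcomes (sustained reentry in TS-50%-HET1/HET2, nonsustained in
TS-11%-HET1) are not reproduced here — the reentry classifier itself is
verified on synthetic and simulated event logs.

Two published results are *not* reproduced by the default
(printed-parameter) model and are reported as failing expectations rather
than adjusted: the TS-50% column of the APD table (including the two EAD
phenotypes) and, as a direct consequence, the mid-wall conduction-block
dichotomy on desk-scale transmural cables (the restitution-compressed
MID-ENDO APD difference at BCL 500 ms stays below the propagation
refractory margin, so premature beats fail at the stimulus rather than
intramurally). Both are recovered qualitatively with the `ts_floor`
extension described above, which is consistent with the incomplete-VDI
electrophysiology of G406R; we keep the printed formulation as the default
because it is the stated parameterisation.

## Known limitations

* No calcium-dependent-inactivation variant of G406R (the mutation acts
  only on VDI), no alternative ionic models, no Purkinje system and no
  patient-specific geometry.
* No unipolar electrograms (extracellular lead fields are out of scope).
* The solver is serial; the study's multilevel Schwarz preconditioning on
  64–128 cores is replaced by Jacobi-PCG honouring the same residual
  contracts, which is adequate at desk scale but not at the full 6.4M-node
  resolution.
* Mass lumping is available for the gauge weights only; the parabolic and
  elliptic solves always use the consistent mass matrix.
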