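---
title: "Water-fat MRI cooling-reheating analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-fat MRI cooling-reheating analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coolbat)
```

## The scientific problem

Brown adipose tissue (BAT) burns lipid to generate heat. In adult humans the
main depot sits in the cervical-supraclavicular region (here "sBAT",
*suspected* BAT, because voxels mix brown and white adipocytes). A
cooling-reheating protocol images a subject with chemical-shift-encoded
water-fat MRI three times — at thermoneutrality (Baseline), after about three
hours of mild cold exposure (Cold), and after roughly fifteen minutes of
reheating (Reheated) — and quantifies, per scan, the fat fraction
FF = F/(F+W) and the effective transverse relaxation rate R2\* = 1/T2\*
within sBAT and within posterior subcutaneous adipose tissue (SAT, a non-BAT
comparator).

The protocol's attribution logic rests on two time-scale assumptions:
perfusion is regulated within minutes, so a perfusion-driven FF change
reverses during the short reheating; lipid stores turn over slowly, so a
consumption-driven FF decrease persists. A cold-induced sBAT-FF decrease
that *remains* after reheating therefore points to lipid consumption rather
than to altered perfusion.

`coolbat` implements the full computational chain of such a study —
multi-echo signal simulation with known ground truth, water-fat/R2\*
reconstruction, VOI segmentation, cross-scan VOI transfer, and the paired
statistics plus attribution rule — so that each stage can be verified
against oracles and the end-to-end chain against the truth of simulated
cohorts.

## The signal model and its simulation

Per voxel and echo time $t_n$, the complex gradient-echo signal is

$$ s(t_n) = \bigl(W + F\,c_n\bigr)\, e^{i 2\pi \psi t_n}\, e^{-R_2^* t_n},
\qquad c_n = \sum_p \alpha_p e^{i 2\pi f_p t_n}, $$

with water and fat amplitudes $W, F \ge 0$, off-resonance $\psi$ (Hz), a
common decay rate $R_2^*$ for both species, and the multi-peak fat
modulation $c_n$. The default acquisition mirrors a 1.5 T neck protocol:
six unipolar echoes, TE1 = 1.68 ms, echo spacing 2.87 ms, TR = 32.7 ms,
flip angle 6°, 1.0 × 1.0 × 2.0 mm voxels. The flip angle is small enough
that T1 weighting is negligible, and T1 is deliberately not modelled.

The fat spectrum ships as a configurable nine-peak triglyceride table
(dominant methylene peak at −3.40 ppm from water, −217 Hz at 1.5 T),
normalized to unit total amplitude and rescaled linearly to the protocol's
field strength. Exact published peak tables differ slightly between
laboratories; what matters for the package's validation logic is that the
simulator and the reconstruction share one table by construction, and every
simulated image and reconstructed map carries the table it used.

Noise is independent complex Gaussian per voxel, echo, and channel
(`noise_sd`, in the phantom's arbitrary units where adipose total signal is
about 1, so `noise_sd = 0.02` corresponds to SNR 50). No coil correlations,
parallel-imaging artifacts, chemical-shift displacement, or motion blurring
are simulated.

## The digital neck phantom

`build_neck_phantom()` evaluates analytic geometry on the scan grid: an
elliptical body cross-section that widens toward the shoulders, a posterior
subcutaneous fat band along the body surface, two interior sBAT ellipsoids
flanked by water-only vessels, a bone-marrow core, and muscle elsewhere.
Because the geometry is analytic, rigid subject motion between scans is
applied *exactly* — the shapes are re-evaluated at inverse-transformed
coordinates — so moved phantoms are not interpolated and ground truth stays
exact under motion.

Within-tissue FF heterogeneity is a smooth zero-mean sinusoidal field fixed
in body coordinates (default SD 0.01 FF, i.e. 1 percentage point), chosen as
a mild, spatially coherent variation of the kind adipose tissue shows;
because it moves with the subject, VOI means remain comparable across
states. The off-resonance field is a smooth low-order polynomial (tens of
Hz across the volume) in scanner coordinates.

What the phantom does *not* emulate is important for interpreting green
tests: there is no partial-volume mixing within a voxel (each voxel is pure
tissue), no true BAT microstructure, no susceptibility-induced field
distortions near tissue interfaces, and no respiratory motion. Threshold
and erosion refinement is therefore exercised by *boundary voxels of other
tissues* inside the crude masks rather than by genuinely mixed voxels.

## Reconstruction: decoupled, multi-scale, regularized

Reconstruction composes three estimators, in the classic decoupled order:

1. **Field map.** Discrete candidates $\psi \in [-1/(2\Delta TE),
   +1/(2\Delta TE)]$ (one aliasing period, ±174 Hz at ΔTE = 2.87 ms) in
   2 Hz steps are scored per voxel by the residual of the linear
   least-squares fit of the demodulated signal to the water-fat basis.
   R2\* is *not* estimated at this stage; its decay is compensated by
   taking the minimum residual over a small nominal set
   (`fieldmap_r_set`, default 0/25/50/100 s⁻¹), which keeps the correct
   $\psi$ basin competitive for strongly decaying voxels. Candidates are
   linked across 6-neighbours by the penalty
   $\mu \sum ((\psi_a - \psi_b)\,\Delta TE)^2$ with $\mu = 10$ by default;
   the data term is normalized per voxel, making the trade-off
   dimensionless. A 3-level coarse-to-fine pyramid (2× block averaging of
   the complex data) solves an exhaustive search plus iterated conditional
   modes (ICM) at the coarsest level — where water-fat swaps are resolved
   globally — and propagates labels down as initialization for windowed
   ICM (±24 Hz) at finer levels.
2. **R2\*.** A per-voxel 1D search over 0–150 s⁻¹ in 0.5 s⁻¹ steps
   minimizes the same fit residual at the estimated $\psi$; a coarse pass
   (every 5 s⁻¹) followed by local refinement gives identical results to
   exhaustive search on the smooth residuals encountered in practice, and
   `r2s_stride = 1` forces full exhaustion.
3. **Amplitudes.** The final linear solve returns complex water and fat
   coefficients; FF is formed from their magnitudes.

After the first R2\* pass, a short refinement re-runs the windowed
field-map ICM with the basis decay fixed per voxel at the estimated R2\*
and then repeats the R2\* search (iterated decoupling). On noiseless data
whose true $\psi$ and R2\* lie on the search grids this restores exact
inversion: FF is recovered to machine precision, which the acceptance suite
asserts at 10⁻⁶.

Numerical conventions, chosen once for determinism:

* Ties in any residual minimization break toward smaller $|\psi|$ (then
  smaller $\psi$) and smaller R2\*.
* With `mu = 0` the full candidate list is always explored, so the result
  equals the exhaustive per-voxel minimizer exactly — the property the
  oracle-equivalence tests check.
* `magnitude_discrimination` resolves *exact* residual ties between a
  candidate and its swap partner (they arise for degenerate single-peak
  spectra) by preferring the fit that explains the voxel as a dominant
  single species.
* Voxels whose fitted total W+F falls below the machine-noise floor are
  flagged degenerate and reported as FF = 0.

## Segmentation and VOI transfer

sBAT VOIs start from crude over-segmenting masks (in the simulator: the
true blob dilated twice, minus the subcutaneous band, mimicking manual
outlining that excludes subcutaneous fat but includes muscle/vessel
boundary voxels). Refinement keeps voxels with FF ≥ 40 % (removes
non-fatty tissue) and R2\* ≤ 50 s⁻¹ (removes partial-volume boundary
voxels), both thresholds inclusive, then applies one pass of 3D erosion
with a six-neighbourhood structuring element; grid-border voxels always
erode. The R2\* ceiling is interpreted in s⁻¹ (equivalently T2\* ≥ 20 ms),
the unit in which R2\* is reported throughout.

The crude baseline VOI is transferred to the other states by rigid
registration (normalized cross-correlation of FF maps, multi-resolution,
deterministic Nelder-Mead refinement with a coarse lattice search and a
feet-head line search — the short slice stack makes the z translation the
least identified parameter) and nearest-neighbour mask resampling;
refinement is then applied on each state's own maps, so small registration
errors are corrected by the thresholds. Transfer-then-refine, and
threshold-then-erode, are deliberate orderings where the underlying
protocol is ambiguous; both are stated here as the package's convention.

Posterior SAT VOIs are computed fully automatically and without
registration in every state: Otsu's threshold on W+F yields a body mask;
per axial slice and left-right column, voxels are collected inward from the
posterior body surface while they pass the same FF/R2\* criteria, to at
most 10 mm depth (parameter); one erosion pass follows. The column scan
keeps the component connected to the posterior boundary and makes the
segmentation translation-equivariant along the left-right axis.

## Cohort generation: the study conditions

`cohort_spec()` defaults encode the emulated study conditions: nine
subjects (eight in the two-scan procedure mode), per-subject baseline
values drawn from normal distributions with group mean ± SD of
82.8 ± 5.0 % (sBAT-FF), 85.2 ± 5.1 % (SAT-FF), 21.0 ± 1.8 s⁻¹ (sBAT-R2\*)
and 19.6 ± 2.8 s⁻¹ (SAT-R2\*); a persistent lipid-type sBAT-FF cold effect
of −1.94 ± 1.83 pp; a null-ish SAT-FF cold effect of 0.23 ± 0.53 pp; a
posture-related SAT-FF drift of −0.79 ± 0.27 pp applied between the Cold
and Reheated scans regardless of temperature (−0.75 ± 0.64 pp between the
two scans of the procedure mode); a reversible sBAT-R2\* cold effect of
0.65 ± 0.88 s⁻¹ and a persistent SAT-R2\* cold effect of 0.40 ± 0.46 s⁻¹.
Lipid-type effects persist through reheating; perfusion-type effects
reverse; the perfusion component defaults to zero so that mechanism studies
switch it on explicitly. Inter-state subject motion is rigid with
translations up to 3 mm in plane (2 mm feet-head) and rotations up to 3°
about the slice axis (1° about the in-plane axes) — magnitudes of ordinary
repositioning; the acquisition protocol gives no measured values, so these
are the package's choice. All randomness derives from the single spec seed;
a fixed seed reproduces cohorts bit-identically.

`simulate_measurements()` bypasses imaging and returns the truth ledger in
measurement format; it is the right tool for power and attribution studies
of the *design*, while `run_cohort_experiment()` measures what the *image
chain* adds.

## Statistics and attribution

All within-subject comparisons use the two-sided Wilcoxon matched-pairs
signed-rank test at α = 0.05, implemented in-package: zeros dropped,
midranks for ties, and an exact p-value from the full null distribution of
the rank sum (generating-function convolution over the doubled midranks)
for effective n ≤ 25 — `stats::wilcox.test` abandons exactness under ties,
which is why the package carries its own implementation; the base-R test
and full 2ⁿ enumeration serve as oracles in the test suite. Above n = 25 a
normal approximation with tie and continuity correction takes over.
p-values in [0.05, 0.10) are reported with a separate "trend" flag that the
attribution rule ignores. No multiple-testing correction is applied,
matching the per-comparison convention of the protocol.

The attribution rule formalizes the verbal time-scale argument as a
function of the three significance flags (Cold−Baseline,
Reheated−Baseline, Reheated−Cold): persistent significant change → lipid;
reverting significant change → perfusion; all three significant → mixed;
no cold effect → none; the remainder → indeterminate. This table is an
interpretation — the underlying argument is verbal — and the direction of
the cold change is reported alongside rather than folded into the rule.

## Problem sizes and verification scope

The package's verification experiments run at a 64 × 64 × 12 demonstration
grid, chosen so that a full three-state, nine-subject cohort — simulation,
reconstruction, registration, segmentation and testing — completes in well
under a minute and replicate recovery experiments (20+ cohorts per mode)
complete within minutes on one CPU. Unit tests use still smaller grids.
The group-statistic recovery experiment regenerates cohorts from the
default effect distributions, runs the full chain, and checks the recovered
group means against the generating means within three replicate standard
errors; `scripts/acceptance.R` reruns exactly this experiment from a seed.

Known limitations, restated plainly: no partial-volume mixing, so the
threshold-and-erosion step is validated against boundary contamination
rather than voxel-level mixing; registration rotation about the in-plane
axes is weakly identified on thin slice stacks (translations are recovered
to sub-voxel accuracy, in-plane rotation to a fraction of a degree on
noiseless data); the statistical power of a nine-subject design at the
default lipid effect size is around 70–80 %, so a single simulated cohort
frequently fails to reach significance even though the effect is real —
averaging over replicates, as the recovery experiment does, is the honest
way to compare recovered and generating means.
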