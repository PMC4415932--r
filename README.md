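# coolbat

Simulation and analysis pipeline for water-fat MRI **cooling-reheating**
studies of brown adipose tissue (BAT).

## The problem

Active BAT burns lipid for heat. In adult humans the main depot is the
cervical-supraclavicular fat ("sBAT" — *suspected* BAT), and mild cold
exposure is expected to lower its fat fraction. Chemical-shift-encoded
multi-echo MRI measures, per voxel,

- the **fat fraction** FF = F/(F+W), where W and F are the water and fat
  signal amplitudes, and
- the effective transverse relaxation rate **R2\*** = 1/T2\*,

from the complex gradient-echo signal
s(TE_n) = (W + F·c_n)·exp(i2πψ·TE_n)·exp(−R2\*·TE_n), with c_n the
multi-peak fat modulation and ψ the off-resonance field. A cooling-reheating
protocol scans each subject at Baseline, after ~3 h of mild cold (Cold), and
after ~15 min of reheating (Reheated). Because perfusion is regulated in
minutes while lipid stores turn over slowly, a cold-induced sBAT-FF decrease
that **persists** after reheating indicates lipid consumption; one that
**reverses** indicates perfusion. Posterior subcutaneous fat (SAT) serves as
a non-BAT comparator.

`coolbat` provides, for this design:

- a digital neck phantom and cohort simulator with exact ground truth
  (`build_neck_phantom()`, `simulate_multiecho()`, `cohort_spec()`,
  `simulate_cohort()`);
- multi-scale regularized water-fat separation with decoupled single-R2\*
  estimation (`reconstruct_maps()`, μ = 10 smoothness default);
- sBAT VOI refinement by inclusive FF ≥ 40 % and R2\* ≤ 50 s⁻¹ thresholds
  plus six-neighbourhood erosion (`refine_voi()`, `erode_6n()`), automatic
  posterior SAT segmentation (`segment_posterior_sat()`);
- rigid registration and VOI transfer across scans (`register_rigid()`,
  `transfer_voi()`);
- exact Wilcoxon matched-pairs statistics and the lipid-vs-perfusion
  attribution rule (`wilcoxon_signed_rank()`, `summarize_protocol()`,
  `attribute_mechanism()`);
- end-to-end orchestration with NIfTI/CSV/JSON products
  (`run_pipeline()`, `run_cohort_experiment()`, `recovery_experiment()`).

## Worked example

Simulate a nine-subject cohort at the default study conditions (a
lipid-type sBAT-FF cold effect of −1.94 ± 1.83 pp that persists through
reheating, and a posture-related SAT-FF drift of −0.79 ± 0.27 pp between
the Cold and Reheated scans), read off its per-subject VOI means, and run
the protocol statistics:

```r
library(coolbat)
m <- simulate_measurements(cohort_spec(seed = 4))
s <- summarize_protocol(m)
s$changes[s$changes$quantity == "ff", ]
#>   voi quantity        transition n mean_change sd_change statistic    p_value
#>  sbat       ff     Cold-Baseline 9  -2.0092644 2.1409791         4 0.02734375
#>  sbat       ff Reheated-Baseline 9  -2.0092644 2.1409791         4 0.02734375
#>  sbat       ff     Reheated-Cold 9   0.0000000 0.0000000         0 1.00000000
#>   sat       ff     Cold-Baseline 9   0.4249137 0.6515027        36 0.12890625
#>   sat       ff Reheated-Baseline 9  -0.5263730 0.7261741         6 0.05468750
#>   sat       ff     Reheated-Cold 9  -0.9512867 0.2062565         0 0.00390625

attribute_mechanism(s$tests[["sbat.ff.Cold-Baseline"]],
                    s$tests[["sbat.ff.Reheated-Baseline"]],
                    s$tests[["sbat.ff.Reheated-Cold"]])
#> Mechanism attribution [sbat ff]: lipid (decrease after cold exposure)
#>   cold_vs_base    mean -2.009, p = 0.02734 *
#>   reheat_vs_base  mean -2.009, p = 0.02734 *
#>   reheat_vs_cold  mean 0.000, p = 1
```

This cohort's sBAT-FF dropped ~2 pp in the cold (exact Wilcoxon p = 0.027,
n = 9), the drop persisted after reheating (p = 0.027 vs Baseline, p = 1 vs
Cold), so the rule attributes it to **lipid** consumption; the SAT-FF
decrease appears only between Cold and Reheated (p = 0.0039), the posture
signature. At n = 9 the test's power at this effect size is ~70–80 %, so
other seeds legitimately return `none`.

The full imaging chain (phantom → multi-echo simulation → reconstruction →
segmentation → registration → statistics) runs through
`run_cohort_experiment(cohort_spec(seed = 1))` (about half a minute for a
64 × 64 × 12 grid cohort), or stage-by-stage with on-disk NIfTI/CSV
products via `run_pipeline(pipeline_config(outdir = "runs/demo"))`.

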