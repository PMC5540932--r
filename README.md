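# lssrm

Task-induced striatal dopamine release from dynamic [11C]raclopride PET,
modeled with a linearized extension of the simplified reference tissue model
(LSSRM).

Raclopride competes with endogenous dopamine at D2 receptors: when a
cognitive task raises dopamine release during a bolus-plus-infusion scan,
ligand binding drops. This package is for researchers analyzing such
displacement studies — e.g. working-memory training experiments asking
whether an intervention changes task-induced dopamine release. It provides:

* **Kinetic modeling.** Forward simulation and linear least-squares fitting
  of the SRTM extended with a gamma-variate activation term:
  `dC_T/dt = R1 dC_R/dt + k2 C_R − (k2a + γ h(t)) C_T`, with
  `h(t) = (τ/tp)^λ exp(λ(1−τ/tp))` (unit peak a fixed time after task
  onset). Baseline and activation binding potentials
  `BP0 = k2/k2a − 1` and `BP1 = k2/(k2a + γ h̄) − 1`, and their difference
  ΔBP, the within-scan displacement effect.
* **Image pipeline.** NIfTI I/O, edge-preserving masked Gaussian smoothing
  (normalized convolution; nothing crosses the mask boundary), 2.5 mm
  motion screening with cohort bookkeeping, reference-region TAC
  extraction, and voxelwise BP parametric mapping restricted to a striatal
  search volume with explicit flagging of non-physical fits.
* **Nonparametric inference.** Sign-flip paired t maps for within-session
  task effects (p < 0.01), and the 2 (group) × 2 (time) permutation ANOVA
  on ΔBP change — a pseudo-t with variance smoothing, maxT family-wise
  correction over the search volume (5000 permutations), and
  cluster-extent filtering (clusters must exceed 5 voxels).
* **Behavioral statistics.** Split-plot mixed ANOVA with partial eta
  squared and Cohen's d from F, pooled two-sample t from printed summary
  statistics, and 3×IQR outlier screening.
* **Synthetic cohorts.** A phantom generator (bolus-plus-infusion input
  function, ~2934-voxel striatal search mask, training-effect sub-region,
  duration-weighted Gaussian noise, motion traces, behavioral tables) so
  the entire pipeline is testable end to end with no scanner data.

## A worked example

Simulate a noise-free target curve on the 20-frame schedule, fit it back,
and compute binding potentials:

```r
library(lssrm)
ref   <- simulate_reference_tac()            # bolus+infusion reference TAC
truth <- kinetic_params(1.0, 0.3, 0.1, 0.02) # R1, k2, k2a, gamma
ct    <- simulate_target_tac(ref, truth, ref_fun = reference_curve())
fit   <- fit_lssrm(ct, ref)
fit
#> Linearized extended SRTM fit
#> R1 = 1, k2 = 0.3 /min, k2a = 0.09999 /min, gamma = 0.01999 /min
#> RSS = 0.044, condition number = 290
binding_potentials(fit$params)
#> BP0 = 2, BP1 = 1.734, delta = -0.2662 (valid)
```

The fitted parameters recover the generating values to a fraction of a
percent, `BP0 = 2` is the baseline binding potential (`k2/k2a − 1`), and the
negative `delta` is the activation-phase drop in binding produced by
`gamma = 0.02` /min — the displacement signal the group analysis tests.

The same stages scale to images: `phantom_spec()` + `simulate_phantom_scan()`
make 4D scans, `masked_gaussian_smooth()` + `fit_voxelwise()` map BP per
voxel, `group_time_anova()` runs the permutation interaction test, and the
`run_simulate()` / `run_fit()` / `run_stats()` trio drives everything from a
YAML config (shell wrapper in `inst/cli/lssrm-pipeline.R`).

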