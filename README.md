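# dceKMC

Quantitative analysis of **ultrafast dynamic contrast-enhanced breast MRI**
(3–9 s per frame) for predicting pathologic complete response (pCR) to
neoadjuvant chemotherapy — before therapy begins.

Aggressive breast tumors secrete angiogenic factors that measurably alter
perfusion in the *normal* parenchyma of the affected breast. dceKMC
quantifies this as **bilateral asymmetry**: ipsilateral-to-contralateral
(I/C) ratios of parenchymal enhancement-kinetic parameters, estimated
stably by clustering voxels with similar uptake before fitting.

## Method at a glance

Per patient (tumor, ipsilateral and contralateral parenchyma handled
separately, from co-registered masks):

1. **Percent signal enhancement** per voxel,
   `PSE(t) = 100 (S(t) − S̄pre)/S̄pre`.
2. **Two-parameter empirical model** per voxel,
   `PSE(t) = A α t² / (1 + α t²)` — A (%) the asymptotic enhancement,
   α (min⁻¹) the uptake rate; `A·α` is the maximum-enhancement-rate proxy.
3. **K-means (K = 5)** on the scalar `A·α` map, clusters relabeled in
   ascending mean `A·α`; deterministic quantile initialization.
4. **Cluster-mean curves** (signal averaged, then converted) fitted with
   the **three-parameter model** `PSE_c(t) = A α t²/(1+α t²) e^{−βt}` and
   integrated to **AUC30** over the first 0.5 min.
5. **Extended Tofts model** on SPGR-inverted concentration curves with a
   population arterial input function:
   `C(t) = v_p C_p(t) + K^trans ∫ C_p(τ) e^{−(K^trans/v_e)(t−τ)} dτ`,
   with `K_ep = K^trans/v_e` per cluster.
6. **Weighted summaries**: parenchyma `(2c₂+3c₃+4c₄)/9`, tumor
   `(3c₃+4c₄+5c₅)/12`, and the I/C ratio of every parameter
   (A, α, A·α, β, AUC30, K^trans, v_e, K_ep, v_p).

At the cohort level: Wilcoxon/chi-square group comparisons, exhaustive
≤3-feature logistic model search over seven feature families (clinical /
tumor-kinetic / asymmetry and their combinations), apparent ROC AUC with
1000-resample bootstrap confidence intervals, paired bootstrap z-tests
between models, and Youden operating points.

Because no patient data are distributed, the package ships a **bilateral
digital phantom** (known voxelwise kinetic truth, exact mirror symmetry at
asymmetry factor r = 1, Rician or Gaussian noise) and a **cohort
simulator** (group distributions of a 56-patient neoadjuvant cohort as
defaults) that every stage is validated against.

## Worked example

```r
library(dceKMC)

# A bilateral phantom with a 1.4-fold ipsilateral A*alpha elevation and
# 2 % Rician noise, through the full per-patient pipeline:
ph  <- generatePhantom(phantomSpec(grid = c(32, 64, 8), r = 1.4,
                                   noiseModel = "rician", noiseSd = 0.02,
                                   seed = 601))
res <- runPatient(ph$series, ph$labels, patient = "demo")
subset(res$summary$parameters, parameter == "Aalpha")
#>   parameter     kbpe_ips    kbpe_con  kbpe_ic       kt_ave
#> 3    Aalpha 104.60467673 74.49656087 1.404154 3169.9858507
```

Running exactly this (seed 601) prints an `A·α` I/C of **1.404**: the
phantom's designed 1.4-fold parenchymal asymmetry, recovered end-to-end
through voxel fitting, clustering, cluster-curve refitting and weighted
averaging. (The `kt_ave` column summarizes tumor clusters 3–5; tumor
enhancement is far stronger than parenchymal, hence the large value. In
this signal-mode phantom only the enhancement-model parameters carry the
designed asymmetry; use `mode = "concentration"` for Tofts-parameter
ground truth.)

```r
# A simulated 56-patient cohort and the model search:
co <- generateCohort(cohortSpec(seed = 11))
cmp <- compareGroups(co, "kbpe_ic_ktrans", nBoot = 0)
cmp$summary            # nonpCR 1.57 +/- 0.63 vs pCR 1.05 +/- 0.13
cmp$p                  # 0.0003
rc <- runCohort(co, nBoot = 1000, seed = 3, families = c("ii", "iii"))
c(rc$models$ii$auc, rc$models$iii$auc)   # 0.708 vs 1.000
```

The parenchymal `K^trans` I/C separates the simulated response groups
(group means 1.57 vs 1.05 on this draw) at rank-sum p = 3e-4, and the
asymmetry-only model family dominates the tumor-kinetics-only family —
the qualitative finding the method is built around. The asymmetry
family's apparent AUC of 1.0 overshoots any real cohort's because the
simulator draws features independently within groups; see the methods
vignette for what the simulation does and does not emulate.

## Layout

- `R/` — S4 classes (`DynamicSeries`, `RegionLabels`,
  `ClusterAssignment`, `PopulationAif`) and the pipeline stages:
  `io_core.R`, `phantom.R`/`cohort.R`, `enhancement_kinetics.R`,
  `clustering.R`, `pharmacokinetics.R`, `summary_asymmetry.R`,
  `stats_prediction.R`, `pipeline.R`.
- `vignettes/methods.Rmd` — the model, assumptions, numerical choices,
  what the phantom does and does not emulate, and known limitations.
- `tests/testthat/` — unit, property and end-to-end validation suites.
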