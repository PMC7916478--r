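# gliomix

Integrated qualitative and quantitative MRI analysis for glioblastoma:
radiomics feature extraction, VASARI-coded qualitative features, stacked Cox
prognostic modelling with external-validation diagnostics, and molecular-
marker prediction by randomized model search — exercised end to end on a
synthetic multi-scanner cohort generator with known ground truth, so no
patient data is required.

## The problem

Glioblastoma outcomes vary widely even among IDH-wild-type patients, and the
clinically relevant molecular markers (MGMT methylation, EGFR amplification,
IDH1 mutation) require tissue. Pre-operative MRI carries both qualitative
information (standardised VASARI scores: multifocality, subependymal
extension, proportion of edema, ...) and quantitative information (radiomics:
first-order, shape and gray-level texture features over original, Laplacian-
of-Gaussian and wavelet-filtered T1+Gd / T2 volumes). This package implements
the full analysis chain that combines those blocks with clinical covariates.

## The models

**Prognosis.** Each feature block is reduced by a univariate Cox screen
(Wald p &le; 0.2), Spearman correlation elimination (|r_s| > 0.85), and
backward elimination (removal &alpha; = 0.2), yielding a per-block Cox model
and its prognostic index

&nbsp;&nbsp;&nbsp;&nbsp;PI = &Sigma;<sub>i</sub> &beta;<sub>i</sub> x<sub>i</sub>,

centred at the training mean. Stacked models refit Cox on the component PIs
(VASARI + radiomics, VASARI + clinical, radiomics + clinical, and all
three). External validation reports Harrell's C with bootstrap CIs, the
calibration slope of the frozen PI (likelihood-ratio test of slope = 1 via an
offset model), a joint misspecification test (signature features refit on
validation with the frozen PI as offset), and a Kaplan–Meier risk split at
the frozen training 75th-percentile PI threshold with model-predicted
group-average survival curves.

**Markers.** Per block: correlation elimination keeping the higher
univariate AUC, frozen Z-scoring, 70/30 stratified split, cumulative
random-forest Gini importance over 1000 randomly parameterised fits (trees
20–300, depth 2–6) selecting the top 20 features, randomized search over
boosted trees / random forests / ridge logistic regression (1000
candidates), repeated-split evaluation of the top 5, refit on the full
cohort, and probability-averaging ensembles of the VASARI and radiomics
arms, with 100-iteration bootstrap AUC CIs.

## Worked example

Plant two prognostic signals (one per block) in synthetic survival data,
run the single-block chains, stack the PIs, and validate:

```r
library(gliomix)
set.seed(1)
n <- 400
blocks <- list(
  vasari    = setNames(as.data.frame(matrix(rnorm(n * 6), n, 6)),
                       c("subependymal_extension", sprintf("v_noise%d", 1:5))),
  radiomics = setNames(as.data.frame(matrix(rnorm(n * 7), n, 7)),
                       c("T2_wavelet.LLH_firstorder_Mean", sprintf("r_noise%d", 1:6))))
gt <- ground_truth(beta_surv = c(subependymal_extension = 0.5,
                                 `T2_wavelet.LLH_firstorder_Mean` = 0.5),
                   censor_rate = 0.02, seed = 1)
surv <- simulate_survival(cbind(blocks$vasari, blocks$radiomics), gt)

m_vasari    <- train_prognostic_block(blocks$vasari, surv)
m_radiomics <- train_prognostic_block(blocks$radiomics, surv)
m_radiomics
#> <gx_cox_model: 2 feature(s), fitted on training (n=400, events=291)>
#>                                  coef     HR     se      p
#> T2_wavelet.LLH_firstorder_Mean 0.4075 1.5031 0.0606 0.0000
#> r_noise4                       0.1211 1.1287 0.0591 0.0404

pis <- data.frame(vasari    = compute_pi(m_vasari, blocks$vasari),
                  radiomics = compute_pi(m_radiomics, blocks$radiomics))
stacked <- stack_pi(pis, surv)
stacked
#> <gx_cox_model: 2 feature(s), fitted on training (n=400, events=291)>
#>             coef     HR     se p
#> vasari    1.1011 3.0075 0.1332 0
#> radiomics 1.1254 3.0813 0.1444 0

hc <- harrell_c(compute_pi(stacked, pis), surv, n_boot = 200)
sprintf("stacked C-index %.3f (95%% CI %.3f-%.3f)", hc$c_index, hc$ci_lower, hc$ci_upper)
#> "stacked C-index 0.682 (95% CI 0.650-0.713)"

km_split(compute_pi(stacked, pis), surv)
#> <gx_km_split at training P75 = 0.4748>
#>   training log-rank p: 4.173e-20
```

The chain kept the planted feature in each block (plus one borderline noise
feature at the liberal 0.2 threshold, as expected), both component scores
enter the stack with hazard ratios near e^1 ≈ 2.7 per score unit, and the
risk split at the training 75th percentile separates survival sharply.

The same machinery runs end to end from images via `gx_run(demo_config())`,
which simulates two multi-scanner cohorts (NIfTI volumes + masks + CSV
tables), preprocesses them (resampling, bias-field correction, histogram
equalization, training-frozen Z-score transfer), extracts the full radiomics
inventory, fits prognostic Models 1–7 and the per-marker classifiers, and
renders a report (C-index forest plot, KM curves with predicted overlays,
ROC curves). A thin CLI covers the same stages:

```sh
inst/cli/gliomix run-all --config config.yaml
```

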