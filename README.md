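# ilc2gate

Reference-based detection of **type 2 innate lymphoid cell (ILC2)
infiltration** in bulk tumour RNA-seq cohorts, with out-of-distribution
gating and survival stratification.

ILC2 are rare GATA3⁺ innate lymphocytes whose tumour infiltration has
been associated with better overall survival in colorectal cancer. They
cannot be counted directly in bulk tumour RNA-seq; `ilc2gate` infers
their presence by training a classifier on sorted innate-lymphoid-cell
reference transcriptomes and applying it to each tumour, then *gating*
the calls so that tumours too dissimilar from the training distribution
are never scored. The package is aimed at computational immunologists
who want this inference chain as tested, reusable components rather than
a one-off script.

## What it computes

Given raw counts `c_gs` with library sizes `N_s`:

* **TMM / logCPM normalisation** — scale factors
  `f_s = 2^(Σ w_g M_g / Σ w_g)` from doubly-trimmed log-ratios
  `M_g = log2((c_gs/N_s)/(c_gr/N_r))` with inverse asymptotic-variance
  weights (matches edgeR to machine precision), and
  `x_gs = log2((c_gs + 0.5)·10⁶ / (N_s f_s + 1))`.
* **Signature selection** — top-*n* highly variable genes of a
  single-cell source (variance of logCPM) intersected with an immune
  gene panel.
* **Boosted L1 linear classifier** — binary logistic loss, 3 boosting
  rounds of soft-thresholded coordinate updates, L1 penalty 0.05,
  stratified 70/30 split; confidence `σ(b + wᵀx)`.
* **Similarity gate** — Euclidean distances `d_k` to the training class
  centroids over the signature genes, RBF similarity
  `s = max_k exp(−γ d_k²)` (γ from the median heuristic by default), and
  the dual call rule **confidence > 0.20 AND similarity > 0.90** (both
  strict).
* **Survival** — Kaplan–Meier curves, log-rank test, and multivariate
  Cox proportional hazards (Efron ties) over age, sex, nodal status,
  stage and the ILC2 call, with Wald 95% CIs.
* **Synthetic data** — negative-binomial reference / single-cell /
  cohort generators with planted infiltration fraction, domain shift and
  true hazard ratio, so every claim above is testable with known truth.

See `vignettes/ilc2-infiltration-pipeline.Rmd` for the model, parameter
rationale and limitations.

## Worked example

Simulate a full input set (3,000 genes, 300-gene panel, 518 patients,
27.8% planted infiltration, true hazard ratio 0.5) and run the whole
pipeline:

```r
library(ilc2gate)
cfg <- sim_config(n_genes = 3000, panel_size = 300, n_patients = 518,
                  true_hr = 0.5, seed = 7)
paths <- write_simulation(cfg, "demo")
rc <- run_config(paths["ref_counts"], paths["ref_labels"], paths["sc_counts"],
                 paths["panel"], paths["cohort_counts"], paths["clinical"],
                 outdir = "demo/out", n_hvg = 600, seed = 7)
report <- run_pipeline(rc)
print(report)
```

Output (abridged):

```
[ilc2gate] panel 'panel.txt': |panel| = 300, |hvg| = 600, |intersection| = 249
[ilc2gate] holdout: accuracy 1.000 on 24 samples (train 56 / test 24)
[ilc2gate] gate: 144 / 518 samples called ILC2-high (tau_conf = 0.2, tau_sim = 0.9)
ilc2gate run: cohort 518 | valid survival 518 | ILC2-high 144
  holdout accuracy: 1.000
  log-rank chi2 = 36.505, p = 1.52e-09
Cox PH fit (Efron ties): n = 518, events = 366
     covariate    beta    hr lower95 upper95     se        p
   age_decades -0.0610 0.941   0.852   1.039 0.0508 2.30e-01
      sex_male -0.1730 0.841   0.683   1.036 0.1062 1.03e-01
 node_positive -0.0549 0.947   0.766   1.170 0.1082 6.12e-01
         stage -0.0294 0.971   0.865   1.090 0.0588 6.17e-01
          ilc2 -0.7414 0.476   0.371   0.612 0.1275 6.03e-09
```

Reading it: the signature is the 249 panel genes that are highly
variable in the single-cell source; the classifier separates the
reference classes perfectly on held-out samples; the gate recovers
exactly the 144 planted infiltrated patients (144/518 = 27.8%); and the
Cox model attributes a protective hazard ratio of 0.48 (95% CI
0.37–0.61) to the ILC2 call — close to the planted true hazard ratio of
0.5 — while the covariates simulated independently of survival stay
near HR 1. Outputs land in `demo/out/`: `gate_results.tsv`,
`survival_report.json`, `model.json`, `run.log`.

The same stages are available as a CLI
(`exec/ilc2gate <simulate|normalize|signature|train|gate|survival|run-all>`).

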