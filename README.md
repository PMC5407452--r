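# baltatlas

Analysis tools for developmental time-series expression atlases of the
human fetal adrenal gland, testis and ovary — the staged (Carnegie
CS17–CS23, fetal F1–F3; ~42–73 days post conception) bulk expression data
in which testis determination, SOX9-like upregulation and the onset of
testicular steroidogenesis play out.

The package is aimed at transcriptomics analysts who want the full
pipeline behind such an atlas as tested, reusable functions: a per-gene
transition model, moderated differential expression with the standard
fold-change screens, batch/QC utilities, candidate gene-set screens, and a
seed-reproducible synthetic atlas generator with planted ground truth so
every stage can be validated without any data download.

## The BALT model

The core is a four-parameter sigmoid describing a gene's log2 expression
*X* over time *t* (dpc):

```
X(t) = B + A / (1 + exp(f(T) · (L − t))),     f(T) = 2·ln(9) / T
```

- **B** (basis): starting expression level (log2);
- **A** (amplitude): signed size of the change — negative for
  down-regulated genes;
- **L** (localisation): inflexion time in dpc, i.e. *when* the gene
  switches;
- **T** (transition): duration of the change in days; with the calibration
  above, `T` is exactly the 10%→90% rise time.

Fitting is bounded Levenberg–Marquardt least squares with multi-start
initialisation (`balt_fit()`); a constant model is compared by BIC
(`select_model()`); parameter uncertainty comes from random-walk Metropolis
MCMC (`balt_mcmc()`); fits are classified into flat / switch / curvilinear
dynamics (`classify_profile()`), summarised into onset windows
(`onset_window()`), and matched against reference profiles such as SOX9
(`match_reference()`).

Around the model sit:

- `fit_group_means()` → `moderate_variances()` → `adjust_bh()` →
  `select_de()`: empirical-Bayes moderated t contrasts with
  Benjamini–Hochberg FDR and the log2FC ≥ 1 / ≥ 2, q ≤ 0.05 screens;
- `quantile_normalize()`, `adjust_batch()` (exact mean/variance or
  ComBat-style empirical-Bayes mode), `detect_outliers()`, `pca_embed()`,
  `cluster_samples()` (Ward.D2);
- `venn_counts()`, `split_early_late()`, `steroidogenesis_candidates()`,
  `chrY_screen()`, `secreted_screen()`, `categorize_candidates()`:
  the set-operation screens that produce candidate lists;
- `build_design()` / `default_truth_panel()` / `simulate_atlas()`: the
  synthetic study-mirror atlas (53 samples: 17 adrenal, 20 testis,
  10 ovary, 6 controls) with flat, tissue-offset, sigmoid, curvilinear and
  SRY-like pulse truth profiles, batch effects and Gaussian noise;
- `run_pipeline()`: the whole workflow end to end, writing TSV/text
  outputs and a JSON run log, bit-for-bit reproducible per seed. A thin
  CLI wrapper lives in `inst/scripts/atlas-cli.R`.

## Worked example

```r
library(baltatlas)

design <- build_design("study_mirror", seed = 1)     # 53 samples
sim    <- simulate_atlas(design, default_truth_panel(n_flat = 80), seed = 1)
mat    <- adjust_batch(sim$matrix, design$batch)

# fit the BALT model to a planted steroidogenic gene on the testis course
tes   <- design$sample_id[design$tissue == "testis"]
times <- design$age_dpc[match(tes, design$sample_id)]
select_model(times, mat["STERO01", tes])
#> <balt_fit> model = sigmoid
#>       B       A       L       T
#>  5.7751  5.9689 54.6795  2.8042
#> rss = 2.083  n = 20  converged = TRUE
#> delta BIC (constant - sigmoid) = 78.4
```

The gene (planted with B = 6, A = 6, L = 54.8, T = 3) is recovered as a
sigmoid switching at ~54.7 dpc — inside the 54–57 dpc steroidogenesis-onset
window — with the sigmoid preferred over a flat model by ΔBIC ≈ 78. The
adrenal-vs-control contrast ranks the same planted genes on top:

```r
tab <- moderate_variances(
  fit_group_means(mat, design$tissue, c("adrenal", "control"))
)
head(top_table(tab, 3)[, c("gene", "log2fc", "t", "q")])
#>      gene log2fc    t        q
#> 6 STERO05   6.80 37.6 2.68e-32
#> 8 STERO07   6.46 38.4 1.71e-32
#> 2 STERO01   5.73 38.7 1.50e-32

log2fc_to_absfc(6.85)   # log2FC 6.85 <-> absolute fold change 115.4
#> [1] 115.4015
```

Here `log2fc` is the difference of group mean log2 expressions, `t` the
empirical-Bayes moderated t statistic and `q` the BH-adjusted p-value; the
planted amplitudes (4–7 log2, i.e. 16–128-fold) are recovered with
essentially zero false-discovery contamination.

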