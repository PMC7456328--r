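# respmf

Similarity-constrained low-rank matrix factorization for predicting
anticancer drug response.

Pharmacogenomic screens such as GDSC and CCLE measure log IC50 — the log
half-maximal inhibitory concentration — for panels of cancer cell lines
treated with anticancer drugs, leaving many cell line–drug pairs unmeasured.
`respmf` is for computational biologists who want to impute and predict
those responses from molecular side information: it factorizes the masked
response matrix $R_{n\times m}$ into latent matrices $P_{n\times k}$,
$Q_{m\times k}$ with $r_{ij}\approx p_i q_j^\top$, while a graph-Laplacian
manifold penalty keeps similar cell lines (by expression, copy number or
mutation profile) and similar drugs (by fingerprint, target proteins or
pathway membership) close in latent space:

$$
L=\tfrac12\sum_{(i,j)\,\mathrm{obs}}(r_{ij}-p_iq_j^\top)^2
+\tfrac{\mu}{2}\big(\lVert P\rVert_F^2+\lVert Q\rVert_F^2\big)
+\tfrac{\lambda}{2}\Big(\sum_{i,j}\lVert p_i-p_j\rVert^2\,\mathrm{SimC}_{ij}
+\sum_{i,j}\lVert q_i-q_j\rVert^2\,\mathrm{SimD}_{ij}\Big)
$$

minimized by alternating exact block-Newton updates, with a second run on
$R^\top$ averaged into the final prediction. Around the core the package
provides the full pipeline: expression-distance-weighted KNN imputation,
Pearson/Jaccard similarity construction with symmetric-normalized-Laplacian
scaling, repeated cross-validation with RMSE/$R^2$/PCC and the fitness
score $R^2+\mathrm{PCC}-\mathrm{RMSE}$, grid-search tuning, a 1-NN
baseline, tissue-wise redundancy removal, pathway-activity association, and
quartile-based sensitive/resistant calling — plus a seeded synthetic data
generator with known ground truth, so everything is testable offline.

## Worked example

```r
library(respmf)

dataset <- simulate_dataset(n = 60, m = 12, k = 3, sigma = 0.1,
                            missing_fraction = 0.2, seed = 42)
simC <- build_similarity(dataset$expr)   # Pearson over expression profiles
simD <- build_similarity(dataset$chem)   # Jaccard over fingerprints

hyper <- mf_hyperparams(k_percent = 50, mu = 8, lambda = 2, seed = 1)
pred <- predict_dual(dataset$response, simC, simD, hyper)
glance(pred$fit_forward)
#> # A tibble: 1 × 6
#>       k    mu lambda n_iterations converged final_loss
#>   <int> <dbl>  <dbl>        <int> <lgl>          <dbl>
#> 1     6     8      2            7 TRUE            422.

cv <- cross_validate(dataset$response, simC, simD, hyper,
                     n_folds = 5, n_repeats = 2, seed = 7)
cv
#> <eval_report> 5-fold CV x 2 repeats: RMSE 1.0894, R2 0.6320, PCC 0.8693, fitness 0.4119

head(cv$per_drug_pcc, 3)
#> # A tibble: 3 × 3
#>   drug     pcc n_obs
#>   <chr>  <dbl> <int>
#> 1 drug01 0.922    46
#> 2 drug02 0.915    49
#> 3 drug03 0.940    49

calls <- call_sensitivity(pred$combined, dataset$response$observed)
head(calls, 4)
#> # A tibble: 4 × 4
#>   drug   cell    predicted call
#>   <chr>  <chr>       <dbl> <chr>
#> 1 drug01 cell029     -1.67 sensitive
#> 2 drug01 cell032     -1.55 sensitive
#> 3 drug01 cell025     -1.26 sensitive
#> 4 drug01 cell049     -1.15 sensitive
```

The fit converges in 7 alternating updates; held-out 5-fold CV recovers the
planted responses with Pearson correlation 0.87 on this small noisy
instance (0.99 at the default generator size, see below). Per-drug
correlations show the drug-wise view used for scatter diagnostics
(`plot_drugwise()`), and `call_sensitivity()` labels the most/least
responsive quartiles of each drug's unmeasured cell lines.

`autoplot()` works on fitted objects (loss trace) and CV reports (per-fold
metric boxplots); `tidy()`/`glance()` return tibbles throughout. A thin
command-line front end over the same functions ships in
`inst/scripts/respmf-cli.R` (subcommands `simulate`, `impute`, `similarity`,
`fit`, `predict`, `cv`, `tune`, `purify`, `pathway`, `call`).

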