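# nbsig

Mutational-signature extraction from SBS96 count matrices by
**Negative Binomial non-negative matrix factorization with
patient-specific dispersion**, with a robust, cross-validation-style
procedure for choosing the number of signatures.

## Who this is for

Cancer-genomics analysts who start from a patients × 96 trinucleotide
mutation count matrix and want (i) signatures and exposures under a noise
model that tolerates the overdispersion real tumor cohorts show, (ii) a
defensible choice of the number of signatures, and (iii) residual
diagnostics that say whether the Poisson or Negative Binomial model
actually fits their data.

## The model

Counts are factorized as `V ≈ W H` with row-stochastic signatures `H`
(K × 96) and nonnegative exposures `W` (N × K). Instead of the classical
Poisson assumption, each patient gets their own dispersion:

    V_nm ~ NB(mean = (WH)_nm,  Var = (WH)_nm (1 + (WH)_nm / α_n))

As `α_n → ∞` this recovers Poisson NMF. At fixed dispersions, maximum
likelihood in `(W, H)` minimizes the divergence

    d_N(V ‖ WH) = Σ_nm [ V log(V/Λ) − (α_n + V) log((α_n + V)/(α_n + Λ)) ],
    Λ = WH,

which the package minimizes by majorization–minimization multiplicative
updates (monotone descent, Poisson KL updates as the `α → ∞` limit).
Fitting is staged: Poisson NMF → per-patient (or pooled) dispersion MLE by
Newton–Raphson on log α → NB updates at fixed dispersions, best of five
random initializations throughout.

Rank selection (`sigmos()`): for each candidate K, repeatedly hold out 10%
of patients, refit on the rest, align training signatures to the full-data
signatures by optimal cosine assignment, predict the held-out patients
from their *full-data* exposures and the training signatures, and score
with the generalized KL divergence; the K with the lowest median held-out
cost wins. AIC/BIC are provided for comparison — on overdispersed data a
Poisson-likelihood AIC/BIC buys extra signatures to absorb the unmodelled
variance, while the held-out procedure stays on target.

## Worked example

```r
library(nbsig)

# a benchmark-style cohort: 100 patients, 5 signatures (SBS1 + SBS5 forced),
# NB exposures (mean 6000, dispersion 1.5), NB noise with alpha = 10
cfg <- simulation_config(n_patients = 100, n_signatures = 5,
                         noise = "negbin_fixed", alpha = 10, seed = 42)
sim <- simulate_dataset(cfg)

fit <- nb_nmf(sim$counts, K = 5, mode = "patient", seed = 1)
fit
#> Signature factorization fit
#>   model      : negbin_patient
#>   rank K     : 5
#>   patients   : 100  mutation types: 96
#>   divergence : 4539.7663 (max_iter reached)
#>   loglik     : -47222.902
#>   dispersion : per patient, median 10.2298

# recovered signatures vs the simulation truth
m <- match_signatures(sim$true_H, fit$H)
round(m$similarity, 4)
#> [1] 0.9969 0.9982 0.9954 0.9972 0.9978

# does the NB variance structure fit? (~95% of cells inside +/- 2 sd)
residual_report(sim$counts, fit)$coverage_fraction
#> [1] 0.9663542

# how many signatures does the held-out cost support?
sel <- sigmos(sim$counts, "negbin_patient", k_grid = 2:8, J = 10, seed = 1)
sel$chosen_k
#> [1] 5
```

The cosine similarities say each true signature was recovered nearly
exactly; the coverage near 0.95 says the fitted Negative Binomial variance
matches the data (a Poisson fit to the same counts covers only 0.47 of
cells at ±2σ — the overdispersion signature); the selection returns the
true rank.

A command-line wrapper with `simulate` / `fit` / `select` / `residuals` /
`match` subcommands is installed at `inst/cli/nbsig`:

```sh
Rscript inst/cli/nbsig fit --counts counts.tsv --model nb --k 5 --seed 1 --out fit/
```

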