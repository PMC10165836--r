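---
title: "Negative Binomial NMF for mutational signatures: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative Binomial NMF for mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsig)
```

## The model

A mutational count matrix $V \in \mathbb{N}_0^{N \times M}$ holds, for each
of $N$ patients, the number of somatic single-base substitutions in each of
$M = 96$ trinucleotide contexts. Non-negative matrix factorization
approximates $V \approx WH$ where the rows of $H \in \mathbb{R}_+^{K\times M}$
are *signatures* (probability vectors over mutation types) and
$W \in \mathbb{R}_+^{N \times K}$ holds per-patient *exposures*.

The classical probabilistic reading is Poisson,
$V_{nm} \sim \mathrm{Po}((WH)_{nm})$, whose maximum likelihood estimate
minimizes the generalized Kullback–Leibler divergence. Real tumor genomes
are overdispersed — the mutation probability varies along the genome and
between patients — so this package models

$$V_{nm} \sim \mathrm{NB}\!\left(\alpha_n,\;
  \frac{(WH)_{nm}}{\alpha_n + (WH)_{nm}}\right),
\qquad
\mathbb{E}[V_{nm}] = (WH)_{nm},\quad
\mathrm{Var}(V_{nm}) = (WH)_{nm}\Bigl(1 + \frac{(WH)_{nm}}{\alpha_n}\Bigr),$$

with a *patient-specific* dispersion $\alpha_n > 0$: patient-to-patient
variability in mutational burden is far larger than variability between
mutation types. Small $\alpha_n$ means strong overdispersion; as
$\alpha_n \to \infty$ the Poisson model is recovered. A shared-dispersion
variant sets $\alpha_1 = \dots = \alpha_N$.

At fixed dispersions, maximizing the NB likelihood is equivalent to
minimizing the divergence

$$d_N(V \| WH) = \sum_{n,m} \Bigl\{ V_{nm}\log\frac{V_{nm}}{(WH)_{nm}}
 - (\alpha_n + V_{nm})\log\frac{\alpha_n + V_{nm}}{\alpha_n + (WH)_{nm}}
 \Bigr\},$$

which is nonnegative and vanishes exactly at $V = WH$
(`nb_divergence()`, `nb_loglik()`).

## Fitting

`nb_nmf()` follows a three-stage procedure:

1. **Poisson NMF** (`poisson_nmf()`) with the standard KL multiplicative
   updates gives initial fitted means $\widehat{WH}$.
2. **Dispersion MLE** (`estimate_dispersion()`): each $\alpha_n$ (or one
   pooled $\alpha$) maximizes the NB likelihood at those fixed means.
   Newton–Raphson runs on $\theta = \log\alpha$ (positivity for free),
   initialized at the method-of-moments value from the variance formula
   above, with a bracketed golden-section/Brent fallback on
   $\log\alpha \in [\log 10^{-3}, \log \alpha_{\mathrm{cap}}]$ when a
   Newton step is unstable. When the score is still positive at the
   ceiling $\alpha_{\mathrm{cap}} = 10^5$ the data show no overdispersion
   and the estimate is reported at the cap — "effectively Poisson". The
   cap is far above per-patient estimates seen in practice (a breast-cancer
   patient in the tens of thousands), so it never truncates a meaningful
   estimate.
3. **NB MM updates**: with dispersions held fixed, $W$ and $H$ alternate
   through the multiplicative updates

   $$H_{km} \leftarrow H_{km}
     \frac{\sum_n W_{nk}\, V_{nm}/(WH)_{nm}}
          {\sum_n W_{nk}\, (V_{nm}+\alpha_n)/((WH)_{nm}+\alpha_n)},$$

   and symmetrically for $W$. These are majorization–minimization steps:
   each update minimizes a surrogate that upper-bounds $d_N$ and touches it
   at the current iterate, so the divergence trace is non-increasing — a
   property the test suite checks on randomized instances rather than by
   proof. With $\alpha_n \to \infty$ they collapse to the Poisson updates.

Dispersions are estimated **once**, from the Poisson-stage means, and not
re-estimated inside the NB iteration; `refit_dispersion = TRUE` recomputes
them once at the end for reporting only. This follows the staged procedure
the model was designed around, and keeps the MM descent guarantee intact
(the divergence is only monotone at fixed $\alpha$).

### Numerical choices

* All fitted means and update denominators are floored at
  $\varepsilon = 10^{-10}$; $0\log 0 = 0$ throughout.
* Initial $W, H$ entries are i.i.d. uniform on $(0,1]$, rescaled so
  $\mathrm{mean}(WH) = \mathrm{mean}(V)$. Five random initializations per
  fit (the default throughout), seeded `seed + i`; the winner is the
  lowest final divergence, ties to the lowest init index.
* Multi-start screening: every initialization runs to tolerance
  $\max(\texttt{tol}, 10^{-5})$ and only the winner is refined to the
  requested tolerance. Local optima of the divergence are separated by
  gaps orders of magnitude larger than the screening refinement, so the
  race picks the same winner as full runs while skipping most of the
  losers' tail iterations.
* Convergence: relative divergence change
  $|d_t - d_{t-1}| / \max(1, d_{t-1}) < 10^{-8}$, at most $10^4$ outer
  iterations. Non-convergence at `max_iter` is reported, not an error.
* $H$ is made row-stochastic only at output time, with the inverse scale
  folded into $W$ so $WH$ is unchanged; the updates themselves operate on
  unconstrained nonnegative factors.
* The compiled inner loop is plain dense linear algebra; the one-step R
  functions `nb_update_H()`/`nb_update_W()` define the update and the test
  suite checks the compiled iteration against their composition.

## Choosing the number of signatures

`sigmos()` selects the rank by repeated patient splitting. For each
candidate $K$: fit the full matrix once; then, $J = 10$ times, fit the NMF
on a random 90% of patients, align the training signatures to the
full-data signatures by maximum-total-cosine assignment
(`match_signatures()`, exact assignment — a greedy match can misalign
similar signatures), and predict the held-out patients as
$W_{\mathrm{test}} H_{\mathrm{train}}$ using the *full-data* exposures of
the test patients. The median over splits of the held-out generalized KL
cost is the score for $K$; the minimizing $K$ wins, ties to the smaller
$K$ (parsimony). Test-set exposures are deliberately not re-estimated from
the training signatures — re-estimation overfits the held-out patients.
Frobenius and Itakura–Saito costs are available behind a flag; costs are
never comparable across models (the gKL cost itself favors the Poisson
model), which is why model choice rests on residual diagnostics instead.

Design details that the procedure's description leaves open, decided here:

* $J = 10$ splits by default; medians stabilize quickly and each split
  costs a full NMF fit.
* Test sets are drawn independently per split ($\lceil 0.1N \rceil$
  patients without replacement), not as a $K$-fold partition.
* The $J$ splits are drawn once per call and reused for every candidate
  $K$, so rank comparison is not confounded by split noise.
* The NMF fits inside `sigmos()` and `select_rank_ic()` default to a
  looser solver tolerance ($10^{-5}$) than standalone fits: the rank
  decision rests on held-out cost differences that are orders of magnitude
  larger than the final refinement of the objective, and the looser
  tolerance leaves the chosen rank unchanged while keeping the procedure's
  runtime proportionate.

`information_criteria()` implements the classical alternatives
$\mathrm{AIC} = -2\ln L + 2 n_{prm}$ and
$\mathrm{BIC} = -2\ln L + \ln(n_{obs})\, n_{prm}$ with $n_{obs} = N$.
The parameter count is $K(N+M)$ for Poisson, plus $N$ (patient-specific)
or $1$ (shared) dispersion parameters; published analyses rarely state
their counting convention, so this one is documented and deliberately
simple (normalization constraints are not subtracted — the choice shifts
all candidates equally and rarely moves the argmin). On overdispersed data
with a Poisson likelihood both criteria buy extra signatures to absorb the
unmodelled variance and overestimate $K$; the held-out procedure is far
more robust to this misspecification, which the acceptance checks
reproduce on simulated data.

## Residual diagnostics

`residual_report()` computes raw residuals $R_{nm} = V_{nm} - (WH)_{nm}$,
the model standard deviation $\sigma_{nm}$ ($\sigma^2 = \mu$ for Poisson,
$\mu(1+\mu/\alpha_n)$ for NB), Pearson residuals $R/\sigma$, and the
fraction of cells inside $\pm 2\sigma$. "Two standard deviations" is the
band definition (a band of two *variances* would not be dimensionally
comparable to residuals). Pearson residuals are compared against standard
normal quantiles at configurable probabilities (default 2.5%/97.5%): at
the count magnitudes of real SBS96 data the NB/Poisson distributions are
well approximated by a normal with matching moments, making coverage near
95% the signature of a well-specified variance model. A Poisson fit to
overdispersed counts shows heavy-tailed Pearson residuals and clearly
depressed band coverage — the package's criterion for preferring the NB
model on real data. For NB fits the report also tabulates
$\sigma(\mu)$ band curves at the median, smallest and largest estimated
patient dispersion.

## The simulation generator

`simulate_dataset()` reproduces the benchmark design the methods were
validated on:

* signatures: $K$ rows drawn from a catalog, always including SBS1 and
  SBS5 (the two signatures shared across essentially all cancer types),
  the rest sampled without replacement — or symmetric Dirichlet draws;
* exposures: i.i.d. NB with mean 6000 and dispersion 1.5 (heavy-tailed
  mutational burden, as estimated from real cohorts);
* counts: each cell resampled around $(WH)_{nm}$ — Poisson, NB with shared
  $\alpha \in \{10, 200\}$, or NB with per-patient
  $\alpha_n \sim U(10, 500)$. Resampling (rather than adding a noise term)
  is the only construction under which $\mathbb{E}[V] = WH$ holds exactly
  for a count distribution.

The shipped catalog (`synthetic_catalog()`) contains ten *synthetic*
row-stochastic SBS96 profiles labelled SBS1–SBS10 so catalog-mode
simulation works offline; they mimic the sparsity of real consensus
signatures but are not estimates of them, so similarity checks against
this catalog validate the machinery, not concordance with the public
consensus set. Everything is a deterministic function of the seed
(Mersenne–Twister, recorded in every manifest).

What the generator does *not* emulate: correlated exposures between
similar signatures, hypermutated outlier patients, mutation-type-specific
dispersion, and sequencing/calling artifacts. Passing tests on this
generator therefore demonstrate correctness of the estimators under the
stated model, not robustness to everything real cohorts contain.

## Desk-scale validation

The acceptance checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` rerun the package's headline claims at reduced
replicate counts, chosen as the smallest scales at which the claims are
sharp: 20 replicate datasets per dispersion scenario for the
dispersion-MLE recovery ranges (each $N = 100$, $K = 5$), 10 datasets for
the rank-selection robustness rate at $\alpha = 200$, and 10 for the
AIC-overestimation direction at $\alpha = 10$. Published min/max recovery
ranges come from larger replicate counts, so containment at 20 replicates
is the conservative direction. Validation against the two public clinical
cohorts (21 breast, 286 prostate patients) runs only when the user
downloads and supplies those matrices; nothing else depends on them.

## Known limitations

* Dispersion is per patient, never per mutation type; indel/doublet
  contexts are out of scope.
* The NB updates assume fixed dispersions; joint $(W, H, \alpha)$ descent
  is not attempted.
* NMF is non-convex and non-unique; five restarts mitigate but do not
  eliminate local optima, and signature identifiability degrades when true
  signatures are highly similar.
* `match_signatures()` supports $K \le 20$ (exact assignment by dynamic
  programming over subsets).
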