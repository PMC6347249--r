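---
title: "Leverage-score column selection: model, guarantees, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leverage-score column selection: model, guarantees, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcss)
```

## The model

Data enter as a non-negative matrix **A** with *n* cells as rows and *d*
features as columns (typically *n* < *d*; when the opposite holds the
same machinery applies to **A**ᵀ, filtering cells instead). The rank-k
subspace leverage score of column *aᵢ* is the quadratic form

$$\tau_i(A_k) = a_i^\top (A_k A_k^\top)^+ a_i,$$

with $A_k = U_k \Sigma_k V_k^\top$ the best rank-k approximation of
**A**. Equivalently, $\tau_i$ is the squared norm of the minimum-norm
least-squares solution of $A_k x \approx a_i$ — a measure of how much of
the rank-k column space column *i* is responsible for — and, most
usefully for computation, the squared norm of the *i*-th row of $V_k$.
All three forms are implemented: the row-norm form is the production
path (`leverage_scores`, O(ndk) via a truncated SVD), and the
pseudoinverse and least-squares forms are retained as exported test
oracles; the suite checks all three agree to 1e-8 on random matrices.
Scores satisfy $0 \le \tau_i \le 1$ and $\sum_i \tau_i = k$, are
invariant to positive rescaling of **A**, and split across collinear
columns — the property that distinguishes them from per-column scores.

Selection (`dcss_select`) is greedy and deterministic: sort columns by
descending $\tau$, take the shortest prefix $\Theta$ with
$\sum_{i \in \Theta} \tau_i > k - \varepsilon$ (strict), pad to
$|\Theta| = k$ if the stopping rule fired earlier (flagged as
`forced_fill`), and report the threshold $\theta$ (the score of the last
kept column) and the realized leftover mass
$\tilde\varepsilon = k - \sum_{i\in\Theta}\tau_i < \varepsilon$.

Under the interpretation that the columns are i.i.d. draws from the
degenerate Gaussian $N(0, A_k A_k^\top)$, $\tau_i$ is the Mahalanobis
term of column *i*, so the greedy rule keeps the columns whose removal
costs the least likelihood, and the submatrix and full-matrix
log-likelihoods differ by exactly
$\tilde\varepsilon/2 + \tfrac{k(d-|\Theta|)}{2}\log 2\pi +
(d-|\Theta|)\sum_j \log\sigma_j$. `likelihood_identity_check` computes
both sides independently and reports the residual (tolerance 1e-6; in
practice it is at machine precision).

## Runtime-verifiable guarantees

A DCSS submatrix **C** satisfies the Loewner bounds
$(1-\varepsilon)A_kA_k^\top \preceq U_kU_k^\top CC^\top U_kU_k^\top
\preceq A_kA_k^\top$ and the two-sided variant with upper factor
$(1+\varepsilon)$, plus the Frobenius corollary
$(1-\varepsilon)\lVert A_k\rVert_F^2 \le \lVert C\rVert_F^2 \le
\lVert A\rVert_F^2$. Because every matrix in the Loewner statement acts
within the k-dimensional space spanned by $U_k$, the n × n orderings
reduce *exactly* to k × k ones: with $G = U_k^\top C C^\top U_k$ and
$D = \mathrm{diag}(\sigma^2)$, each ordering holds iff the corresponding
difference matrix has smallest eigenvalue ≥ 0. `verify_spectral_bounds`
works in that basis (the suite cross-checks the reduction against the
dense n × n construction on small matrices) and reports the most
negative eigenvalue of each difference as a slack, with pass threshold
$-10^{-8}\sigma_1^2$ — scaling the tolerance by $\sigma_1^2$ makes the
verdict invariant to the size and scale of the input. The same report
detects genuine violations: dropping the toy matrix's $\tau = 1$ column
produces a decisively negative lower slack.

## Parameters

* **k** — the rank of interest. No automatic choice is made: the elbow
  heuristic on the spectrum of $AA^\top$ is a judgment call, so
  `eigenvalue_scan` returns the eigenvalues for inspection plus the
  index of the largest consecutive-ratio gap as a hint (ratios are only
  evaluated down to the numerical rank, with near-zero trailing
  eigenvalues clamped, so noise beyond the rank cannot produce a hint).
* **ε** — the error tolerance, unitless, on the same scale as the
  leverage mass k. Smaller keeps more columns; values used in practice
  are 0.05–0.1. ε ≥ k is permitted (the stopping rule is immediately
  satisfied and the fill-to-k applies). Equivalently one may fix the
  column budget and read off the realized ε̃.
* **centering** — off by default: scoring operates on raw counts, which
  is the workflow the method targets, and preserves non-negativity.
  `center_columns` is available when a variance interpretation of the
  Frobenius bound is wanted.
* **rank tolerance** — a column-space direction is considered present
  when its singular value exceeds 1e-10 × σ₁; requesting k beyond the
  numerical rank is an error naming the achievable rank.

## Numerical conventions

* **Determinism.** The SVD backend is LAPACK's exact dense
  decomposition; singular-vector signs are fixed by making the
  largest-magnitude entry of each right vector positive, so repeated
  runs and serialized artifacts are identical.
* **Ties.** Sorting uses a stable descending order with ties broken by
  ascending column index; this is a policy choice (the selection rule
  itself does not dictate one). The strict `>` in the stopping rule is
  taken literally: a prefix whose mass equals k − ε exactly keeps
  adding. Exact ties are knife-edge events in floating point, so the
  suite exercises them only with binary-exact scores.
* **Baselines.** Count is the column sum; thresholding by the mean
  orders columns identically for a fixed number of cells, so only count
  is exposed. Variance uses the population convention (divide by n).
  Index of dispersion is variance/mean with 0/0 defined as 0, ranking
  all-zero columns last.
* **Randomized sampling.** `random_leverage_sample` draws t columns
  i.i.d. with replacement proportional to τ; duplicates are collapsed
  for the submatrix and multiplicities kept in the returned object, with
  no reweighting of retained columns.
* **Degenerate inputs.** Zero columns carry zero leverage and are
  selected last; all-zero cells are rejected where a probability mass
  function is required, with the offending identifiers named.

## The evaluation harness

The question the harness answers: does the submatrix workflow cluster
cells the way the full-matrix workflow does? Each cell's count vector is
normalized to a probability mass function; pairwise distances are
Jensen-Shannon: $D_{JS}(p,q) = \sqrt{\tfrac12 KL(p\|m) + \tfrac12
KL(q\|m)}$ with $m = (p+q)/2$ and **base-2 logarithms**, so
$D_{JS}\in[0,1]$ and is a metric. The base and the square root are
deliberate, documented choices — they change the similarity
$S = 1 - D_{JS}$ — made so that disjoint supports give exactly
$D_{JS}=1$. Spectral clustering uses the *symmetric* normalized
Laplacian $L = I - \mathrm{Deg}^{-1/2} S\,\mathrm{Deg}^{-1/2}$ (one of
several "normalized Laplacian" dialects; this one keeps L symmetric so
its eigendecomposition is exact), embeds into the `k_embed` eigenvectors
of smallest eigenvalue (default `k_embed = n_clusters`), and runs seeded
k-means with 10 internal restarts; embedded rows are not re-normalized
by default (a flag exists). Agreement is the adjusted Rand index,
implemented from the contingency-table formula and cross-checked in the
suite against a brute-force pair-counting oracle and an independent
reference implementation.

`concordance_experiment` runs the full pipeline on the complete matrix
and on each selection, with T seeded k-means restarts (seeds
`seed..seed+T-1`), and reports mean/sd ARI of each submatrix workflow
against the complete-data workflow at the same seed, treating the
complete-data clustering as the reference. Cells emptied by a selection
have no PMF; they are dropped from both labelings for that comparison
and counted in the report. The distance matrix is dense n × n: fine to a
few thousand cells, and the documented memory contract of the harness.

## The synthetic generator

`simulate_counts` emulates the traits of single-cell count data that
matter for leverage-based selection: a few informative columns with
block structure, a large background of low-abundance noise columns,
non-negative sparse counts, and a steeply decaying sorted leverage
profile. Cells are assigned to clusters round-robin (cluster sizes exact
and reproducible) and each informative feature marks one cluster:
Poisson(50) counts in its own cluster, Poisson(0.5) elsewhere; noise
features are Poisson(0.5) everywhere. The defaults — 200 cells, 30
informative + 500 noise features, 3 clusters — are desk-scale stand-ins
for real experiments: large enough for the planted structure to dominate
the spectrum, small enough that the whole concordance experiment runs in
seconds. Poisson noise is the simplest defensible count model; the
generator deliberately omits dropout/zero-inflation, library-size
variation, and batch structure, so passing concordance tests show the
pipeline is faithful to planted low-rank structure — not that DCSS
conquers those real-data pathologies. The Gaussian likelihood identity
is an interpretation of the selection rule, not a claim about count
distributions.

On those defaults, the suite's stochastic checks (fixed seeds 0–9) are:
the top-30 leverage ranks recover ≥ 90% of the planted informative
columns; the DCSS (k = 3, ε = 0.1) workflow reproduces the complete-data
spectral clustering with mean ARI ≥ 0.9 over 10 restarts; and a
50-column noise-only selection scores at chance (|ARI| ≤ 0.2).

## Power-law diagnostics

Sorted leverage profiles of expression data typically decay as
$\tau_{(i)} \approx b\,i^{-a}$; when $a > 1$ the closed form
$|\Theta| = \max\big((2k/\varepsilon)^{1/(a-1)},
(2k(a-1)/\varepsilon)^{1/(a-1)} - 1, k\big)$ predicts the selection
size, and the comparison bound
$t \ge (2/\varepsilon^2)(k + m\gamma)(1 + \varepsilon/3)\ln(16k/\delta)$
gives the with-replacement sampling budget for the same two-sided
accuracy (m zero-leverage columns, γ the smallest positive score, δ the
failure probability) — deterministic selection wins whenever the first
expression is smaller. `fit_power_law` estimates *a* by ordinary least
squares of $\log\tau_{(i)}$ on $\log i$ over the top-n scores (intercept
included, unweighted; the estimator is a package choice, and R² is
reported so the user can judge the decay assumption). The exponent is
stored decay-positive: a profile falling as $i^{-2}$ fits $a = 2$.
`power_law_profile` generates exact power-law profiles for testing; note
that a profile rescaled to sum to k can demand leading scores above 1,
which genuine leverage scores cannot attain — such profiles are clipped
at 1, renormalized, and flagged, and are then no longer exact power
laws. Round-trip identities are therefore only asserted for unclipped
configurations.

## Limitations

* Dense SVD and dense JS distance matrices: designed for matrices up to
  roughly 10⁴ cells and a few times 10⁴ features on a workstation; no
  out-of-core or GPU path.
* The concordance protocol treats the complete-data clustering as the
  reference; with noisy real data that reference mixes signal and noise,
  so a high ARI means fidelity, not biological correctness.
* No modeling of dropout or zero-inflation; leverage scores operate on
  the counts as given.
* Choosing k remains a judgment; the package surfaces the spectrum and
  a gap hint only.
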