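---
title: "Similarity-constrained NMF for drug-disease association prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-constrained NMF: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcnmf)
```

## The model and its assumptions

Known drug indications form a binary matrix $A \in \{0,1\}^{n \times m}$
over $n$ drugs and $m$ diseases. A 1 is a curated association; a 0 is
*unknown*, not a confirmed negative — the model has no missing-data
semantics beyond that, and every cell of $A$ enters the loss. The
working assumption is the usual one for collaborative filtering of
biomedical networks: associations are driven by a small number of
latent mechanisms, so $A$ is approximately low-rank, and biologically
similar drugs (or diseases) share latent profiles.

`bcnmf()` fits non-negative factors $X \in \mathbb{R}^{k \times n}$,
$Y \in \mathbb{R}^{k \times m}$ minimizing

$$
L(X, Y) \;=\; \lVert A - X^{\top}Y \rVert_F^2
\;+\; \mu\,(\lVert X \rVert_F^2 + \lVert Y \rVert_F^2)
\;+\; \lambda\,(\lVert X^{\top}X - S_d \rVert_F^2
             + \lVert Y^{\top}Y - S_e \rVert_F^2),
\qquad X, Y \ge 0 .
$$

The Tikhonov term ($\mu$) bounds the factor norms and guards against
overfitting the many zeros. The similarity term ($\lambda$) ties the
factor Gram matrices to the supplied drug–drug and disease–disease
similarity networks: two drugs with high $S_d$ entry are pushed toward
similar latent vectors, which is the mechanism by which a drug with few
known links still receives informative scores (the cold-start case).
With $\lambda = 0$ the model is Tikhonov-regularized NMF, and with
$\mu = \lambda = 0$ plain NMF; `objective_value()` and the update rules
reduce exactly to those special cases, which the test suite verifies
term by term.

Similarity matrices are required to be canonical — symmetric,
non-negative, unit diagonal — because the update numerators must stay
non-negative and because $X^{\top}X$ is compared to $S_d$ entrywise.
`canonicalize_similarity()` enforces this (symmetrize by averaging,
clip negatives, set the diagonal to 1) and is idempotent; the reader
warns whenever a file needed repair.

## Optimizer

The non-negativity constraints are handled the standard way for NMF:
the Karush–Kuhn–Tucker conditions of the constrained problem yield
elementwise multiplicative updates,

$$
X \leftarrow X \circ
  \frac{YA^{\top} + 2\lambda\,XS_d}
       {YY^{\top}X + \mu X + 2\lambda\,XX^{\top}X + \varepsilon},
\qquad
Y \leftarrow Y \circ
  \frac{XA + 2\lambda\,YS_e}
       {XX^{\top}Y + \mu Y + 2\lambda\,YY^{\top}Y + \varepsilon},
$$

alternated once per sweep ($X$ first, then $Y$ with the new $X$). Every
quantity in numerator and denominator is non-negative, so iterates stay
non-negative, and an entry that reaches exactly 0 stays 0
(zero-locking). The guard $\varepsilon$ (default $10^{-12}$) only
prevents 0/0; it is far below the scale of any active denominator
entry.

Unlike the classical reconstruction-only updates, the similarity term
is quartic in the factors and the update is not derived from a
majorizing surrogate, so monotone descent is not guaranteed by theory.
The package treats descent as an empirical regression guard: the
recorded objective trace is checked to be non-increasing (relative
slack $10^{-8}$ per step) across seeded instances in the test suite,
and a first-order stationarity diagnostic (`kkt_residual()`, the
largest entry of $\min(X, \partial L/\partial X)$ and its $Y$
counterpart) is checked to be $\le 10^{-3}$ after tight convergence on
a small instance.

**Initialization.** Factors start as i.i.d. uniform$(0,1)$ draws from a
seeded stream, multiplied by one global scale factor chosen by a
deterministic one-dimensional line search (`stats::optimize`) on the
objective. A fixed scale that only matches the magnitude of $A$ (such
as $\sqrt{\overline{A}/k}$) sits far below the scale favored by the
unit-diagonal similarity constraints, and the first multiplicative
sweep then overshoots the objective by several percent before
descending; the scale-balanced start removes this and reaches
noticeably lower objectives in the same iteration budget. The line
search is deterministic, so fits remain bitwise reproducible given the
seed, and the fitting functions restore the caller's RNG state.

**Stopping.** Iteration ends at `max_iter` (default 1000) or when the
relative objective change falls below `tol` (default $10^{-6}$),
whichever comes first; the trace (objective after initialization and
after every sweep) is returned for inspection. `max_iter = 0` returns
the bare initialization with a length-1 trace.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 50 | latent dimension; must be below $\min(n,m)$. Dimensionless; larger $k$ fits more structure and overfits sparser data. |
| `mu` | 0.1 | Tikhonov weight, in units of squared score per squared factor norm. |
| `lambda` | 0.1 | similarity weight; 0 ignores the networks entirely. |
| `max_iter` | 1000 | sweep budget. |
| `tol` | $10^{-6}$ | relative objective-change stop. |
| `eps` | $10^{-12}$ | denominator guard. |
| `seed` | 1 | initialization seed; the only source of randomness in a fit. |

No published setting of $k$, $\mu$, $\lambda$ or the iteration budget
exists for the gold-standard benchmarks, so the defaults are modest
round values that behave well on the synthetic benchmark, and
`grid_search()` is provided to tune them by cross-validated AUC on
whatever dataset is at hand. Benchmark metrics quoted elsewhere for
models of this family should be expected to require such tuning.

## Evaluation protocol

`cross_validate()` partitions the positive cells into `n_folds` folds
(default 10, balanced to within one cell, seeded). Per fold it hides
the fold's positives, refits, scores every cell, and evaluates the
hidden positives against **all** unknown cells as negatives; training
positives are excluded from the test pool. This all-unknowns protocol
matches how the model is used — the unknown pairs are exactly the
candidate pool being ranked — and is why specificity and accuracy run
high while precision and F1 stay moderate: the negative class is
enormous and almost entirely easy.

Metric conventions, each pinned against a brute-force oracle in the
tests:

* **AUC** — normalized Mann–Whitney statistic; tied scores count 1/2
  (midranks).
* **AUPR** — step-wise precision–recall area with thresholds at every
  distinct score and no interpolation; with constant scores it equals
  the positive prevalence.
* **Acc/Sen/Spe/Pre/F1** — confusion tallies at `score >= threshold`;
  any ratio with a zero denominator is reported as 0 and flagged. The
  threshold is chosen per fold to maximize F1 (ties broken toward the
  higher threshold) and recorded in the report, so a fixed cutoff can
  be substituted by calling `threshold_metrics()` directly.

Ranking (`rank_candidates()`) excludes known links, sorts by
descending score and breaks ties lexicographically by disease
identifier — determinism across platforms is worth more than any
pretense of resolving a genuine tie.

## The synthetic benchmark

`simulate_bundle()` exists so the whole pipeline is testable without
external data. It emulates the *structure* of the gold-standard
repositioning benchmarks — a sparse binary association matrix of a few
hundred rows/columns with low-rank latent structure, plus similarity
matrices consistent with that structure:

* planted factors $X^{\!*}, Y^{\!*}$ of rank `k_true`, entries drawn as
  the 6th power of uniform$(0,1)$ deviates and columns normalized to
  unit Euclidean norm. The power transform makes loadings right-skewed,
  so each drug or disease is dominated by a few latent components, as
  entities belonging to a few functional categories are. Dense uniform
  loadings would concentrate all columns around one direction, the
  score matrix would be effectively rank one, and its binarization
  would carry almost no recoverable structure;
* $A$ set to 1 on exactly the top `density`$\cdot nm$ cells of
  $X^{*\top}Y^{\!*}$ (ties broken by cell index), so the positive count
  is exact and fixture assertions are tight;
* $S_d = \mathrm{canon}(X^{*\top}X^{\!*} + E)$, with $E$ symmetric
  Gaussian noise of sd `sim_noise` (upper triangle drawn, mirrored),
  and likewise $S_e$. At `sim_noise = 0` the similarities are exactly
  the planted cosine similarities.

Randomness is drawn in the fixed order $X^{\!*}$, $Y^{\!*}$,
$S_d$-noise, $S_e$-noise, so $A$ is identical across noise levels at a
given seed and noise sweeps are matched experiments.

What the generator does **not** emulate: the degree heterogeneity, the
block/ontology structure and the heavy-tailed similarity distributions
of real chemical-structure or phenotype networks, nor curation biases
in which associations get recorded. Passing the recovery experiments
therefore demonstrates that the implementation recovers the structure
its own model class generates — a necessary correctness check — and
not that any particular AUC will be reached on a real benchmark.

## Experiment sizes

The package's standing experiments use a 100 drugs × 80 diseases
benchmark with `k_true = 8`, density 0.1 (800 links): 10-fold CV at
$k = 8$ for the recovery run (mean held-out AUC ≈ 0.96), and 5-fold CV
on five matched seeds for the noise sweep over
`sim_noise` $\in \{0, 0.5, 2\}$, where mean AUC degrades monotonically
(≈ 0.96 → 0.94 → 0.80). Descent and non-negativity are checked over
500 sweeps on ten 60 × 40 instances, and stationarity on a 10 × 8
instance run to `tol` $= 10^{-10}$. These sizes make every property
cheap to re-verify while staying large enough that the CV metrics are
stable to a few points; all of them are re-computed, never quoted, by
the tests and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Shapes are validated eagerly with the offending operand named;
  non-finite inputs are rejected.
* An all-zero association matrix warns and proceeds (with
  $\lambda = 0$ the factors collapse toward 0, as they should).
* `k >= min(n, m)` is a configuration error: the model is only
  meaningful as a low-rank completion.
* Association files must be exactly binary; the reader reports the
  offending cell by row/column label. The spreadsheet-style layout
  (header row of disease ids, first column of drug ids) is accepted in
  either orientation via the `orientation` flag, defaulting to
  drugs-as-rows.
* Similarity canonicalization is applied on read and on fit entry;
  because it is idempotent, already-canonical matrices pass through
  bitwise unchanged.
* Prediction tables are written with 6 significant digits — more than
  the stability of the scores warrants, few enough to round-trip
  exactly through the reader.

## Known limitations

* The optimizer finds a local minimum; different seeds reach different
  (similar-quality) solutions. The factorization is identifiable at
  best up to permutation and scaling of components.
* Descent of the objective is an empirical property here, not a
  theorem; the test suite would catch a regression, but pathological
  inputs violating it cannot be ruled out.
* Treating all unknown cells as negatives during evaluation
  underestimates performance to the extent that true-but-unrecorded
  associations sit in the negative pool — unavoidable without curated
  negatives.
* The model uses one similarity matrix per side; multi-source
  similarity fusion, and any construction of similarities from
  chemical structure or phenotype ontologies, is out of scope.
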