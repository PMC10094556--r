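---
title: "pathsar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathsar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsar)
```

## The model

`pathsar` quantifies how the components of a compositional mixture (the
motivating system: flavan-3-ol monomer units of proanthocyanidins, with
terminal/extension position encoded in names like `ECt` vs `ECe`) relate to
a measured bioactivity, while accounting for the strong correlations the
components have with one another.

With all variables standardized (mean 0, sd 1), the standardized multiple
linear regression

$$y' = \sum_{j=1}^m b_j^* x_j' + \varepsilon$$

is assumed, with $x \sim N(0, R_{xx})$ and i.i.d. normal errors independent
of $x$. Least squares gives the canonical equations

$$\hat R_{xx}\, b^* = \hat R_{xy},$$

whose row $j$ decomposes the total effect (the plain Pearson correlation
$r_{jy}$) into the direct effect $b_j^*$ and indirect effects $r_{jt}
b_t^*$ through each correlated component $t$:

$$r_{jy} = b_j^* + \sum_{t \ne j} r_{jt} b_t^*.$$

This identity holds *algebraically* whenever $b^*$ solves the system; the
package asserts it (to 1e-10) on every pipeline run. The model's
substantive assumptions — linearity on the standardized scale,
approximately multivariate normal components, independent homoskedastic
errors — matter for the F test and for interpreting coefficients, not for
the identity itself.

Interpretation layer:

- **Importance** is $|r_{jy}|$ (closer to 1 = more important); ranking is
  stable under ties (input column order preserved).
- **Influence mode** is `direct` iff $|b_j^*| > |\sum_{t\ne j} r_{jt}
  b_t^*| + \text{margin}$, else `indirect`. The field phrase is "direct
  effect far greater than the total indirect effect"; no margin is ever
  quantified in the sources we know, and every published call in the
  bundled case study is reproduced by the plain comparison, so the margin
  defaults to 0 and is exposed as a parameter.
- **Importance categories** cut $|r_{jy}|$ at descending boundaries,
  inclusive on the upper side. The defaults (0.88, 0.70) are *inferred*
  from the bundled case study's three groups (a category-1 unit sits
  exactly at 0.88, category 3 is "< 0.7"); they are configurable and should
  be chosen per application. A unit's overall category across two
  activities is the better (min) of its per-activity categories, so the
  "major units" set is a union, matching how the case study groups each
  unit once.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` (F gate) | 0.01 | probability | the "extremely significant" convention of the motivating study; the decomposition is computed regardless, artifacts are only flagged |
| `include_threshold` (chart) | 0.7 | correlation | correlation paths below it are hidden purely for readability |
| `band_bounds` (chart) | (0.85, 0.75) | correlation | red/orange band edges used by the motivating figures; edges in [0.70, 0.75) are drawn gray — a band the sources leave undefined, documented as our choice |
| `category_boundaries` | (0.88, 0.70) | correlation | inferred, see above |
| `margin` (influence mode) | 0 | effect size | see above |
| `cond_threshold` (solver) | 1e10 | condition number | beyond it a plain solve is numerically meaningless at double precision given sampling noise; the error names the most collinear column pair |
| `ridge` | NULL | diagonal loading | never applied silently; when supplied it is echoed in outputs |

## Numerical choices

- **Standardization** uses the unbiased (n−1) standard deviation.
  Correlations — the only quantities consumed downstream — are identical
  under the n and n−1 conventions, so this choice is cosmetic and the
  maximum-likelihood (n) convention would give the same $\hat R$.
- **Preprocessing** defaults to `none`. Any positive per-column affine
  transform is a no-op on correlations (tested as a pipeline invariant),
  so magnitude differences between columns are harmless by themselves;
  `log10_offset` is offered for genuinely nonlinear compression and must be
  requested explicitly. Multiple assay columns for one activity can be
  merged as the mean of standardized assays (`combine_activities`), also
  only on request.
- **Solving** uses Cholesky with a `solve()` fallback, a relative residual
  check (1e-8), and a mandatory condition-number diagnostic: mixtures of
  co-occurring monomer units are routinely collinear (many $|r| > 0.9$), so
  silent solves are a trap. R² is reported raw (`r_squared_raw`) and
  clipped to [0, 1] for the F statistic, which uses the exact F
  distribution, not a chi-square approximation.
- **Degenerate inputs**: zero-variance columns, duplicated columns
  (singularity flag + warning), n < 3, n ≤ m + 1 (decomposition reported,
  F test refused) are all caught with specific condition classes.

## Recovering effects from rounded published tables

Published decomposition tables print the block $C$ with $C_{tj} = r_{jt}
b_t^*$ and the direct effects on the diagonal, rounded (typically to 4
decimals). Two distinct tasks arise when the raw data are unavailable:

1. **Reconstructing $\hat R_{xx}$** (`reconstruct_from_published_table`):
   each off-diagonal $r_{jt}$ has two quotient estimates, $C_{tj}/b_t^*$
   and $C_{jt}/b_j^*$. They are symmetrized by a reliability-weighted mean
   with weights $\propto |b^*|$, because a quotient through a tiny diagonal
   (e.g. a direct effect of −0.003) turns half-unit rounding into errors of
   order 0.02. The weighted form reduces algebraically to
   $(\mathrm{sign}(b_t^*) C_{tj} + \mathrm{sign}(b_j^*) C_{jt}) /
   (|b_t^*| + |b_j^*|)$, which never divides by a small number. Entries are
   clipped to [−1, 1]; if eigenvalues fall below −1e-6 the matrix is
   projected to the nearest correlation matrix (eigenvalue clipping,
   diagonal rescale) and the projection distance reported. The
   pre-symmetrization asymmetry is attached as a diagnostic.
2. **Recovering $b^*$** (`recover_direct_effects`): the obvious route —
   solve $\hat R_{xx} b = \hat R_{xy}$ on the reconstructed matrix — is
   numerically doomed for collinear systems: with condition numbers around
   1e5 (both bundled tables), quotient-level rounding noise is amplified to
   order-one errors, including sign flips. The package instead solves the
   *same equations* after multiplying row $t$ by $b_t^*$: since
   $C = \mathrm{diag}(b^*) R_{xx}$ exactly before rounding,
   $R_{xx} b^* = R_{xy} \iff (C - \mathrm{diag}(R_{xy}))\, b^* = 0$.
   The printed $C$ is known to ~1e-4 absolute (no quotients are taken), and
   for both bundled tables the matrix $K = C - \mathrm{diag}(R_{xy})$ has a
   four-orders-of-magnitude gap between its two smallest singular values,
   so the null direction — the direction of $b^*$ — is stable. The scale is
   fixed by least squares of $\hat R_{xx}(\alpha v) \approx \hat R_{xy}$;
   the printed diagonal is never read. A spectral-gap diagnostic is
   attached and a warning raised when the null direction is poorly
   identified (gap < 10).

```{r recover}
tabs <- bundled_paper_tables()
b <- recover_direct_effects(tabs$antioxidant)
round(b[c("ECGe", "ECGt")], 4)
attr(b, "spectral_gap")
```

## The synthetic-data generator

`synthetic_spec` + `simulate_dataset` implement exactly the stated model:
$x \sim N(0, R_{xx})$ via an eigenvalue factorization (so exactly singular
targets still work), $y = \sum b_j x_j + \varepsilon$. Defaults in tests
mirror the motivating design where one exists: 36 samples when emulating
the 6 fractions × 6 repetitions layout, 10 units with the case-study
names. For the parameter-recovery property (m = 10, n = 5000, noise sd 0.1,
exchangeable r = 0.3 — sizes stated with the property itself) the true
coefficient vector is not stated anywhere, so it was fixed once as
(1.0, −0.8, 0.6, −0.4, 0.3, −0.2, 0.15, −0.1, 0.05, 0): a realistic spread
of large, small, negative and exactly-zero effects. Recovery is judged
against the true coefficients on the *sample*-standardized scale,
$b_j \,\mathrm{sd}(x_j)/\mathrm{sd}(y)$, i.e. conditionally on the realized
standardization — comparing against the population scale would add scaling
noise that the coefficient standard errors do not describe.

What the generator does **not** emulate: compositional closure (real
abundance vectors may be constrained to sum to a total), non-normal or
heteroskedastic measurement error, the block structure induced by
polymerization-degree fractions (the `design` field is carried but not used
by the generator), and nonlinearity. A green simulation test therefore
establishes correctness of the estimator under the stated model, not
robustness to those violations.

## Known limitations

- No standard errors or confidence intervals for individual path
  coefficients are reported (the interpretation layer follows the
  point-estimate convention of the field); the test suite computes OLS
  standard errors only to validate the estimator.
- The raw data behind the bundled case study were never published; all
  case-study numbers are desk-scale recomputations from the rounded
  printed tables, with the tolerance budgets that rounding implies
  (cells to 0.02, summary rows to 0.01, recovered direct effects far
  tighter in practice).
- `reconstruct_from_published_table` requires at least two non-tiny direct
  effects and cannot recover the correlation between two units whose direct
  effects are both numerically zero.
- The F test assumes i.i.d. sampling; with repeated measures per fraction
  (the bundled design) it is anticonservative to an unknown degree, which
  is one more reason the significance gate warns rather than aborts.
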