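---
title: "Cumulative environmental health disparities scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative environmental health disparities scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehdscreen)
```

## The model

`ehdscreen` implements a relative, rank-based cumulative-impact screen for
census tracts, in the CalEnviroScreen family of tools. The conceptual model
is risk-scoring:

$$\text{Final Score} = \underbrace{\text{Pollution Burden}}_{\text{threat}}
  \times \underbrace{\text{Population Characteristics}}_{\text{vulnerability}}$$

Indicators fall into four categories. *Environmental exposures* (e.g. diesel
emissions, PM2.5, traffic density) measure pollutants populations contact
directly; *environmental effects* (e.g. proximity to hazardous-waste or
Superfund facilities) measure degraded environmental quality near a
community; *sensitive populations* (cardiovascular disease, low birth
weight) capture intrinsic biological vulnerability; *socioeconomic factors*
(poverty, linguistic isolation, race/people of color, ...) capture extrinsic
vulnerability that modifies resilience to pollution. The bundled default
registry (`load_registry()`) ships 19 indicators: 5 exposures, 5 effects, 2
sensitive-population and 7 socioeconomic.

### Decile scoring

Every indicator is reduced to a decile score per tract, from rank-order of
the raw values alone:

$$d_i = \left\lceil \frac{B \,\bar r_i}{m} \right\rceil \in \{1,\dots,B\},
  \qquad B = 10,$$

where $\bar r_i$ is the tract's average rank (ties share the average of the
ranks they occupy) among the $m$ tracts with a non-missing value, after
multiplying by the indicator's `direction` so the top decile always means
the greatest burden. This rule is deterministic and symmetric in ties: ten
distinct values map to 1–10; a column of identical values maps every tract
to decile 6 (average rank 5.5, $\lceil 5.5 \rceil = 6$). Nothing downstream
ever sees the raw units, so the entire pipeline is invariant under strictly
increasing transformations of any indicator column — a property the test
suite checks end to end.

### Aggregation

Category averages are arithmetic means of the available (non-missing)
deciles of each category's active indicators. Then

$$\text{PB} = \frac{\overline{\text{exposures}} + w\,\overline{\text{effects}}}{1 + w},
\qquad
\text{PC} = \frac{\overline{\text{sensitive}} + \overline{\text{socioeconomic}}}{2},$$

with $w = 0.5$ by default: effects indicators are proximity proxies for
exposure and are half-weighted for that uncertainty. Dividing by the sum of
weights $1 + w$ makes the maximum attainable Pollution Burden exactly 10,
consistent with the stated maxima of both composites; an alternative
`literal_two` mode divides by 2 instead (maximum 7.5 at $w = 0.5$) for
users who want the aggregation exactly as the defining formula is often
printed. The final score $\text{PB} \times \text{PC} \in [1, 100]$ is
deciled once more — the same tie rule — into the final disparities rank,
10 marking the highest cumulative impact. The rank is relative to the
supplied panel only; there is no external reference distribution.

### Missing data

Missingness is never imputed. A missing raw value gives a missing decile; a
category average uses whatever indicators are present (configurable through
`min_category_coverage`, default: any one suffices); a tract with an
entirely missing category gets missing composites and drops out of the
final ranking, with the decile bins formed over the scored tracts only.
This follows the view that silent imputation in an equity screen is worse
than an explicit gap.

## Sensitivity analyses

Two audits are provided for the indicator set.

**Spearman redundancy screen.** `correlation_screen()` computes all
pairwise Spearman correlations (average ranks, pairwise deletion) and flags
pairs as *moderate* ($0.5 \le |\rho| \le 0.8$) or *high* ($|\rho| > 0.8$).
The boundary at exactly 0.8 is taken as moderate; exact boundary values are
vanishingly rare in continuous data and the convention is documented rather
than consequential. Constant columns give an explicit "undefined" flag,
not a number. On panels simulated from the bundled target matrix, the only
highly correlated indicator pair is linguistic isolation with race/people
of color — the tool-design question such a screen informs is whether the
two capture distinct vulnerabilities (they do: information access versus
minority status), not merely whether they co-vary.

**Rank PCA.** `pca_ranks()` replaces each column by its average ranks (so
indicator units drop out), standardises, and runs `prcomp`. With
standardised ranks this is exactly the eigendecomposition of the sample
Spearman correlation matrix, which `variance_explained()` performs directly
on any supplied matrix; centred-but-unscaled ranks would coincide in the
absence of ties, and standardising makes the equivalence exact under ties,
which is why the scaled variant is the default. Loading signs are fixed by
making each component's largest-magnitude loading positive.
`weak_loading_flags()` lists indicators whose maximum absolute loading
across the leading components falls below a threshold (default 0.2 — a
conventional "not loading anywhere" cut, exposed as a parameter since no
canonical value exists); nothing is removed automatically, and a
Kaiser-rule count (`kaiser_count()`) is reported for orientation only.
Component count is likewise left to the user: scree inspection is
judgement, not an algorithm.

Applied to the bundled 17-indicator matrix (the two sensitive-population
indicators excluded, replicating the exclusion such preliminary PCA
passes motivate), the first component carries 28.6% of the variance and
five components carry 67.1%. Eigenvalues of a correlation matrix
transcribed at two decimals can in principle go slightly negative; they
are retained in both shares and trace, and the bundled matrix happens to
be positive-definite (smallest eigenvalue 0.13).

## Synthetic tract panels

`generate_panel()` draws panels with a prescribed pairwise Spearman
structure through a Gaussian copula: the target Spearman matrix is mapped
elementwise to the latent Pearson scale by $\rho_P = 2\sin(\pi\rho_S/6)$,
projected to the nearest positive-semidefinite correlation matrix if the
conversion (or a transcribed target) leaves it indefinite (Higham
projection via `Matrix::nearPD`, perturbation norm reported), factorised,
and sampled; each latent column is then pushed through a marginal quantile
function. Defaults describe the panel this package emulates: 1,500 tracts
(roughly a statewide tract count; nothing depends on it), the bundled
19-indicator target matrix, lognormal marginals for concentration- and
rate-like indicators and beta(2, 5) for percentage-like ones.

Because every published stage of the pipeline is rank-based, matching the
Spearman structure is the right fidelity target and the marginals are
cosmetic: two panels sharing a seed and target but differing in marginals
produce identical score tables, a property the suite asserts. What the
generator does **not** emulate: spatial autocorrelation between
neighbouring tracts, population-size differences, informative (non-MCAR)
missingness, and any higher-order dependence beyond pairwise rank
correlation. Passing tests on synthetic panels therefore validate the
arithmetic and the rank logic of the pipeline, not claims about any real
jurisdiction's geography.

## Equity summaries

`rank_distribution_by_group()` tabulates the final rank's median and
interquartile range within each decile of a grouping indicator (people of
color and poverty being the motivating choices); tracts with missing group
deciles are reported in an explicit `unassigned` bucket rather than
dropped. `identify_high_impact()` flags tracts ranked at or above 9 — the
top 20% when scores are distinct — and `driver_indicators()` lists, per
flagged tract, the individual indicators whose own decile is 9 or 10,
grouped by category and sorted by decile. Spatial clustering of flagged
tracts is deliberately out of scope: any clustering algorithm here would
be an invention, so the package reports the flagged set and leaves spatial
grouping to the analyst.

## Numerical and design notes

* Tie handling (average ranks + ceiling) was chosen over first-occurrence
  ranking for symmetry and determinism; the decile scorer is cross-checked
  against an independent counting oracle over a thousand random tied
  columns.
* All correlation work uses `stats::cor(method = "spearman")`; the
  closed-form $1 - 6\sum d^2 / (n(n^2-1))$ serves as the test oracle on
  untied data.
* Problem sizes in the test and acceptance workloads — 5,000-tract panels
  for copula-recovery checks (sampling error $\approx 3/\sqrt{n} < 0.05$),
  400–4,000 tracts for pipeline properties — were chosen so sampling noise
  is well below the tolerances being asserted.
* GEOIDs are opaque strings end to end (leading zeros preserved, the
  11-character tract convention documented but not enforced), keeping the
  package vintage-agnostic.
* Known limitations: relative ranks only (no absolute risk), no
  resilience/asset indicators by design, no inference on PCA loadings, no
  population weighting.
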