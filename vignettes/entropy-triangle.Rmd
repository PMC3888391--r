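---
title: "Evaluating classifiers with the entropy triangle, EMA and the NIT factor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating classifiers with the entropy triangle, EMA and the NIT factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropytriangle)
```

## The problem: accuracy lies on imbalanced tasks

A multiclass classifier is summarized by its confusion matrix: the
contingency table of counts $n_{ij}$ of joint events "true class $i$,
predicted class $j$". Accuracy — the trace over the total — is the standard
score, but it conflates two very different achievements: learning the
input–output coupling, and exploiting a skewed class prior. A majority
classifier that sends every sample to the most frequent class can post
near-perfect accuracy on imbalanced data while transferring *zero*
information — the accuracy paradox. This package quantifies the distinction
and makes it visible.

## The model

Let $P_{XY}$ be the maximum-likelihood joint distribution $n_{ij}/N$ over
true classes $X$ (cardinality $n$) and predictions $Y$ (cardinality $m$).
With $U_X$, $U_Y$ the uniform references of the same cardinalities, all
entropies in bits, the joint uniform entropy decomposes exactly:

$$\Delta H + 2\,MI + VI \;=\; H(U_X) + H(U_Y)$$

where $MI = H(P_X) + H(P_Y) - H(P_{XY})$ is the mutual information,
$VI = H(X|Y) + H(Y|X)$ the variation of information (the "noise" share),
and $\Delta H = (H(U_X) - H(P_X)) + (H(U_Y) - H(P_Y))$ the divergence from
uniformity (the "imbalance" share). Because $U_X$ and $U_Y$ are independent,
$H(U_X \times U_Y) = H(U_X) + H(U_Y)$, which is the normalization
denominator used throughout — also for $n \neq m$. Dividing through gives
barycentric coordinates $(\Delta H', 2MI', VI')$ on the 2-simplex: the
**entropy triangle**. Its apex holds the best classifiers (all mass in
$2MI'$), its right vertex the specialized majority classifiers (all mass in
$\Delta H'$), its left vertex the worst, uninformative ones (all mass in
$VI'$).

Since $MI$ appears twice in the balance, the equation also splits per
variable, $H(U_X) = (H(U_X)-H(P_X)) + MI + H(X|Y)$ and symmetrically for
$Y$; normalizing each by its own $H(U_\cdot)$ gives the **split triangle**,
one input-side and one output-side point per classifier
(`split_coordinates()`, `plot_split_triangle()`). The $H(U_\cdot)$-weighted
mean of the two split points recovers the joint point, a property the test
suite checks.

### Perplexities, EMA, and the NIT factor

Exponentiating entropies base 2 turns them into *perplexities* — effective
numbers of equally likely classes: $k_X = 2^{H(P_X)}$, the remaining
perplexity $k_{X|Y} = 2^{H(X|Y)}$, and the information transfer factor
$\mu = 2^{MI}$, with $k_X = \mu\,k_{X|Y}$. On these the package builds two
measures:

* **EMA** (entropy-modulated accuracy) $a' = 1/k_{X|Y}$: the accuracy a
  guesser would expect when $k_{X|Y}$ equally likely classes remain
  unresolved after seeing the prediction. Unlike accuracy it is invariant
  to output-label permutations, so a classifier that has learned the
  classes but swapped their names is not punished.
* **NIT factor** $q = \mu/n$: EMA corrected for a non-uniform input prior.
  It equals EMA exactly when $P_X$ is uniform, satisfies
  $1/n \le q \le a' \le 1$, and hits its floor $1/n$ for *any*
  zero-information classifier — including the majority classifier with
  accuracy 1 on fully skewed data. At fixed $n$ it is a monotone function
  of mutual information, so on a shared task EMA and NIT induce the same
  ranking.

We use base-2 logarithms throughout, and $0 \log 0 := 0$ so empty cells,
rows and columns contribute nothing. The NIT denominator is the *input*
cardinality $n$: the correction compensates deviation from uniformity of
the prior class distribution, which lives on $X$. Both conventions are
forced by internal consistency of the published MEG mind-reading table that
ships with the package (`meg_mindreading()`): with them, $1/k_{X|Y}$ and
$\mu/5$ reproduce all ten published EMA and NIT values to the printed 3
decimals, and the reconstructed task perplexity $\mu\,k_{X|Y}$ is constant
(≈ 4.95) across entrants.

## The assessment protocol

```{r protocol}
meg <- meg_mindreading()
report <- evaluation_report(meg, ids = meg$exp, n = attr(meg, "n"))
report
```

1. **Task difficulty**: the reconstructed $k_X \approx 4.95$ (down from 5)
   says the 5-class task is almost balanced, so majority specialization
   cannot pay off.
2. **Ranking**: by EMA the accuracy runner-up at $a = 0.622$
   ($a' = 0.412$) wins; the official accuracy winner ($a = 0.680$,
   $a' = 0.390$) drops to third.
3. **Individual diagnosis**: plot the population on the triangle
   (`plot_triangle()`, color by accuracy, EMA or NIT) and read off
   specialization ($\Delta H'$ side) versus noise ($VI'$ side).
4. **Population verdict**: the best NIT of 0.407 means well under half of
   the transferable information was captured — the task was not effectively
   solved. The report's verdict string uses a qualitative threshold of 0.9
   for "solved"; it is a label, not a statistic.

Ranking ties are broken by descending accuracy and then id order; the
measures themselves define no tie rule, and this one keeps reports
deterministic.

## The confusion-matrix space and the accuracy paradox

`enumerate_matrices(n, N)` generates every $n \times n$ confusion matrix
with total $N$, one representative per reordering of the input classes
(row-sum vector non-increasing): partitions of $N$ into $n$ row sums, then
the Cartesian product of the weak compositions of each row sum into $n$
cells. Partitions keep zero parts, because the most skewed prior
concentrates all mass in one class and must be present. The closed-form
twin `count_matrices()` — $\sum_{\text{partitions}} \prod_i
\binom{N_i+n-1}{n-1}$ — and a brute-force filtered enumeration cross-check
it in the tests. Enumeration order is fixed (partitions and row
compositions in decreasing lexicographic order, rightmost row fastest), so
strided decimation is deterministic and seeded fractional decimation is
reproducible; both are recorded in the output attributes because a
decimated sweep is a *sample* of the space and downstream claims should say
so.

```{r paradox}
sw <- accuracy_sweep(2, 20)
perfect <- sw[sw$accuracy == 1, ]
range(perfect$mi2_norm)
```

Accuracy 1.0 occurs both at $2MI' = 0$ (the majority matrix
$\mathrm{diag}(20, 0)$, NIT $= 1/2$) and at $2MI' = 1$ (the balanced
diagonal, NIT $= 1$); intermediate accuracy levels spread over wide
$2MI'$ ranges. That interspersion — same accuracy, wildly different
information transfer — is the paradox in one picture:
`plot(sw, color_by = "accuracy")`.

The sweep sizes used in examples and tests ($n = 2$, $N \in \{4, 20\}$;
cross-checks up to $n = 3$, $N = 8$) keep the space exact and small; the
space grows combinatorially, so larger specs need `decimation`, and an
undecimated request beyond `max_count` matrices is refused outright.

## Parameters that matter

* `smoothing` (default 0): additive constant on every cell before
  normalizing. The default is the pure maximum-likelihood estimate;
  smoothing is exposed for heavily sparse tables but changes all entropy
  terms, so it is off unless you opt in. No small-sample bias correction
  (Miller–Madow and kin) is attempted.
* `skew`, `fidelity`, `specialize_to`, `seed` in `generate_fixture()`: the
  synthetic generator draws the true-class marginal from a symmetric
  Dirichlet with concentration `skew` (`Inf` = exactly uniform via
  largest-remainder apportionment), places `fidelity` of each row's mass on
  the matching column, and can force a single majority column. It emulates
  the archetypes the triangle separates — faithful, noisy, skewed,
  specialized — with exact marginal control. It does *not* emulate
  structured inter-class confusions (acoustic or semantic similarity
  blocks) or per-class fidelity differences of real classifiers, so
  passing tests certify the measures' algebra and invariances, not any
  claim about particular real data.
* Numerical tolerances: balance and MI-route identities are asserted to
  $10^{-9}$ bits; counts are small integers, there is no catastrophic
  cancellation, and observed errors sit at machine precision
  ($\sim 10^{-15}$). Tiny negative round-off in $MI$ and conditional
  entropies (below $10^{-12}$) is clamped to zero so perplexities never
  dip under 1.

## Degenerate inputs and edge rules

An all-zero table is an error ("empty confusion table"), as is a
$1 \times 1$ task (the normalization denominator $H(U_X)+H(U_Y)$ is zero —
there is nothing to classify). Non-square tables are accepted by every
measure except plain accuracy, which requires matching label sets and
aligns columns to rows *by label*, not position. Real-valued cells are
treated as weights after a warning; only sample-size-dependent statements
(the total $N$) change meaning. An observed accuracy below the clueless
bound $1/\max(n, m)$ flags a label mismatch; `best_label_permutation()`
finds the exact optimal relabelling (exhaustive search to 8 classes, exact
maximum-weight bipartite assignment beyond), and EMA/NIT are invariant
under it by construction.

## Design choices that were genuinely open

* **Triangle orientation**: $\Delta H'$ grows toward the right vertex,
  $VI'$ toward the left, $2MI'$ toward the apex; the interpretive zone
  annotations are drawn as vertex/side labels, not hard regions, because
  the zones are qualitative.
* **Canonical representative** of a matrix orbit: non-increasing row sums.
  Ties in row sums leave multiple row orderings in the space by design —
  they are genuinely distinct matrices over labelled columns.
* **Report rounding**: 3 decimals in written reports, matching the usual
  presentation of perplexity tables; internal computation is full
  precision.
* **CLI**: a thin wrapper (`et_cli()`, `inst/scripts/etcli.R`) over the
  exported functions; everything it prints is reproducible from the R
  console.

## Limitations

Estimates are plug-in maximum likelihood: with very small $N$ the entropy
terms are biased and EMA/NIT inherit that bias; no confidence intervals are
provided. The framework operates strictly at confusion-matrix level — it
cannot recover information a classifier discarded before its output, and it
says nothing about calibration or per-item costs. For tasks where
predictive error on the deployed distribution is the only criterion,
accuracy (or a cost-weighted variant) remains the right score; EMA and NIT
answer the different question of how much of the task's structure the
classifier actually learned.
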