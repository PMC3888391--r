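# entropytriangle

Information-theoretic evaluation of multiclass classifiers from their
confusion matrices: the entropy triangle, the entropy-modulated accuracy
(EMA) and the normalized information transfer (NIT) factor.

## Who this is for

Anyone scoring classifiers on possibly imbalanced data — machine-learning
competition organizers, biostatisticians validating diagnostic or
brain-decoding pipelines, perception researchers with confusion matrices —
who needs to know whether a high accuracy reflects learned structure or
merely an exploited class skew (the accuracy paradox: a majority classifier
posts accuracy 0.9 on 90%-skewed data while transferring zero information).

## The model in brief

For the joint distribution $P_{XY} = n_{ij}/N$ of true classes $X$
(cardinality $n$) and predictions $Y$ (cardinality $m$), with uniform
references $U_X$, $U_Y$ and all entropies in bits, the balance equation

$$\Delta H + 2\,MI + VI = H(U_X) + H(U_Y)$$

splits the joint uniform entropy into divergence from uniformity
$\Delta H$, twice the mutual information $MI$, and the variation of
information $VI = H(X|Y) + H(Y|X)$. Normalized by $H(U_X)+H(U_Y)$, the
triple $(\Delta H', 2MI', VI')$ is a point on a ternary (De Finetti)
diagram — the **entropy triangle**: apex = best classifiers, right vertex =
specialized majority classifiers, left vertex = uninformative ones.

Perplexities $k = 2^H$ (effective class counts) give the two measures:
**EMA** $a' = 1/k_{X|Y} = 2^{-H(X|Y)}$, the expected accuracy against the
classes still unresolved after seeing the prediction, invariant to
output-label permutation; and the **NIT factor** $q = \mu/n = 2^{MI}/n$,
EMA corrected for non-uniform priors, with floor $1/n$ for any
zero-information classifier regardless of its accuracy.

## Worked example

Two classifiers on the same 3-class task with a skewed prior
(180/15/5 samples): a genuine learner and a majority classifier.

```r
library(entropytriangle)
learner  <- confusion_table(rbind(c(170, 6, 4), c(3, 11, 1), c(1, 1, 3)),
                            c("art", "nat", "foot"), c("art", "nat", "foot"))
majority <- confusion_table(rbind(c(180, 0, 0), c(15, 0, 0), c(5, 0, 0)),
                            c("art", "nat", "foot"), c("art", "nat", "foot"))
perplexity_profile(majority)
#> Perplexity profile (n = 3 true, m = 3 predicted, N = 200)
#>   k_X = 1.464  k_Y = 1.000  k_X|Y = 1.464  k_Y|X = 1.000  mu = 1.000
#>   accuracy = 0.900  EMA = 0.683  NIT = 0.333
rank_classifiers(list(learner = learner, majority = majority))
#> Classifier evaluation: 2 classifiers, task perplexity k_X = 1.464
#>  task not effectively solved (best NIT = 0.392)
#>        id k_XgY    mu  acc   ema   nit rank_ema rank_acc
#>   learner 1.246 1.175 0.92 0.803 0.392        1        1
#>  majority 1.464 1.000 0.90 0.683 0.333        2        2
```

Reading the numbers: the majority classifier's accuracy of 0.900 is pure
skew — its transfer factor is $\mu = 1$ (zero mutual information), so its
NIT sits at the floor $1/3$, and on the triangle it lands near the
$\Delta H'$ vertex (`triangle_coordinates(majority)` gives
$(0.83, 0.00, 0.17)$). The learner's extra 2 points of accuracy hide a
real difference: $\mu = 1.175$, NIT 0.392. The task perplexity
$k_X = 1.46$ (down from 3) warns that this prior makes specialization
profitable; neither classifier comes close to solving the task.

The ten entrants of the MEG mind-reading competition (5-class
video-stimulus decoding from magnetoencephalography) ship with the package
as published perplexity columns:

```r
meg <- meg_mindreading()
evaluation_report(meg, ids = meg$exp, n = attr(meg, "n"))
```

Ranking by EMA overturns the official accuracy ranking: the entrant at
accuracy 0.622 (EMA 0.412) wins and the accuracy winner (0.680, EMA 0.390)
falls to third.

Exhaustive sweeps of the confusion-matrix space show the paradox wholesale:

```r
sw <- accuracy_sweep(2, 20)      # all 946 2x2 matrices with N = 20
plot(sw, color_by = "accuracy")  # accuracy 1.0 spans 2MI' from 0 to 1
```

A command-line interface wraps the same functions; see `?et_cli` and the
wrapper at `inst/scripts/etcli.R`:

```sh
Rscript inst/scripts/etcli.R evaluate my_confusion.csv
Rscript inst/scripts/etcli.R sweep --classes 2 --samples 20 --out sweep.csv
```

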