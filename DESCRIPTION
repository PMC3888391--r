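Package: entropytriangle
Title: Information-Theoretic Evaluation of Classifiers with the Entropy Triangle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates multiclass classifiers from their confusion matrices
    using the entropy balance of the joint distribution of true and predicted
    classes. Decomposes the joint uniform entropy into divergence from
    uniformity, twice the mutual information, and the variation of
    information, and plots the normalized triple on a De Finetti (ternary)
    diagram, the entropy triangle. Provides perplexity-based performance
    measures: the entropy-modulated accuracy (EMA) and the normalized
    information transfer (NIT) factor, which are robust to class imbalance
    and to output-label permutations, together with a ranking protocol for
    populations of classifiers. Includes an exhaustive generator of the
    space of square confusion matrices with a fixed sample total (via
    integer partitions and weak compositions), used to demonstrate the
    accuracy paradox, plus file I/O, synthetic fixture generation and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, graphics, stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
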