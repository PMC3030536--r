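Package: fitchacc
Title: Reconstruction Accuracy of Fitch Parsimony on Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of the ambiguous and unambiguous accuracy of
    Fitch parsimony ancestral-state reconstruction at the root of a rooted
    binary phylogeny under the symmetric N-state Jukes-Cantor model. The
    exponential sum over leaf-state configurations is collapsed, by state
    symmetry, into a recurrence over 2N-1 classes of reconstructed state
    sets, giving per-tree accuracies in O(nodes x N^3) time. Includes the
    Fitch algorithm itself, specialized recurrences and asymptotics for
    equal-branch complete binary trees, equal-branch caterpillars and
    Hennigian (ultrametric) caterpillars, the equilibrium threshold of the
    conservation probability, a Yule topology simulator, and brute-force
    enumeration plus Monte-Carlo oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
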