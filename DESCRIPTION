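Package: adawhips
Title: Classification Rule Explanations for Multi-Class AdaBoost
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Explains individual classifications of multi-class AdaBoost
    (SAMME and SAMME.R) models by decomposing the ensemble's decision paths,
    redistributing classifier weights onto individual decision nodes via
    relative entropy, greedily assembling a single high-stability
    classification rule, and attaching probabilistic counterfactual
    contrasts. Includes trainers for boosted shallow entropy-split trees,
    synthetic data generators with known planted structure, a leave-one-out
    evaluation protocol with a regularised precision ("stability") measure,
    and the accompanying significance-testing battery (Cohen's kappa,
    modified Friedman F, Bonferroni post-hoc z).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
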