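Package: mitochronos
Title: Mitogenome Haplogroup Phylogeny, Molecular-Clock Dating and
    Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for matrilineal population history from whole
    mitochondrial genomes: haplotype collapsing and diversity statistics,
    variant calling against a reference coordinate system with effects
    under the vertebrate mitochondrial code, construction of a
    synonymous-only coding alignment (non-synonymous substitutions
    replaced by ancestral bases), maximum-parsimony tree search with
    Fitch mutation mapping, calibrated Poisson molecular-clock dating of
    haplogroup nodes with standard errors and a clock likelihood-ratio
    test, Bayesian skyline inference of effective female population size,
    and a coalescent + HKY+Gamma+I simulator providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
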