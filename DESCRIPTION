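Package: stemsig
Title: Anchor-Specific Gene Signature Discovery and Stemness Index Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers genes whose expression is maximally specific to a
    labeled anchor phenotype (for example pluripotent stem cells) using a
    sliding-window specificity statistic over rank-normalized expression
    profiles, summarizes the coordinated activity of the selected signature
    as the first principal component of the gene-gene covariance matrix (a
    per-sample "stemness index"), and evaluates that index against ordered
    phenotypes such as differentiation time courses and tumor grades.
    Includes per-sample rank normalization, probe-to-gene summarization,
    signature characterization (random-gene-set correlation nulls,
    coexpression module clustering, hypergeometric over-representation),
    seeded synthetic-data generators with planted ground truth, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), mclust, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
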