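Package: oildrop
Title: Fuzzy Oil Drop Analysis of Hydrophobicity Distributions in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes theoretical (T), observed (O), uniform (R) and
    environment-modified (M) per-residue hydrophobicity distributions for
    protein structures under the fuzzy oil drop (FOD) model and its
    environment-aware extension (FOD-M).  The theoretical field is an
    oriented 3D Gaussian fitted to the molecular body; the observed field
    collects intrinsic residue hydrophobicity over spatial neighbours with
    Levitt's distance weighting.  Provides the RD micelle-likeness
    statistic (a Kullback-Leibler divergence ratio), grid selection of the
    environment parameter K, comparative protocols for whole structures,
    chains, domains, fragments and residue-eliminated variants, and a
    deterministic synthetic-structure generator with known hydrophobicity
    organization for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
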