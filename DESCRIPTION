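Package: bioactree
Title: Bioactivity-Based Classification of Target Panels with
    Shared-Active-Compound Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based chemogenomic classification of target
    panels (exemplified on kinase inhibitor screens): per-target
    feature-enrichment profiles with Laplacian correction, bioactivity
    distance matrices (normalized Manhattan on enrichment profiles,
    Tanimoto and Hamming on binary bioactivity fingerprints),
    neighbor-joining trees with Newick interchange, shared-active-compound
    (SAC) score series with quadratic-fit neighborhood classification,
    data-density exclusion filtering, sequence-versus-bioactivity
    cross-tabulation, gatekeeper-residue distance bins, and a SMACOF
    multidimensional-scaling diagnostic. Includes a synthetic panel
    generator with ground-truth cluster, promiscuity and sparsity labels
    so the full two-stage analysis can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
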