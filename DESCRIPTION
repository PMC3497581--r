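Package: acsiva
Title: Assemblage Centroid-Standardized Isotope Vector Analysis
Version: 0.1.0
Authors@R:
    person("ACSIVA", "Developers", email = "acsiva@example.org", role = c("aut", "cre"))
Description: Tools for describing consumer trophic position in stable isotope
    biplot space relative to the local assemblage centroid. Individual d13C/d15N
    signatures are standardized against the unweighted mean of species means at
    each site and summarized as vectors (direction and magnitude). Per-taxon
    circular statistics (mean vector, von Mises concentration, Rayleigh and Rao
    uniformity tests, circular-linear correlation) summarize directional
    preferences, and ancestral niche vectors are reconstructed on a phylogeny by
    branch-length-weighted least squares (squared-change parsimony), with a
    seeded synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
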