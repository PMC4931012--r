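Package: infantgut
Title: Community-State Typing and Fucosyllactose-Utilization Genotype
    Screening for Infant Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the early development of the infant gut
    microbiota from family-level 16S relative-abundance profiles:
    Jensen-Shannon distances, partitioning-around-medoids clustering with a
    subsampled Calinski-Harabasz cluster-number voting procedure, principal
    coordinates analysis, longitudinal community-state transition analysis,
    Mann-Whitney cluster characterization with compact letter displays,
    Spearman co-occurrence networks between taxa and gut-environment
    variables, and a pan-genome presence/absence concordance screen that
    relates strain genotypes (ortholog-group membership) to human-milk
    oligosaccharide growth phenotypes. Includes a synthetic cohort and
    strain-panel generator with planted structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
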