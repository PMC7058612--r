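Package: mitolandscape
Title: Mitochondrial Genome Variant Structure, Haplogroups, Imputation
    and Phenome-Wide Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale characterization of the human
    mitochondrial genome from whole-genome sequencing: haploid variant
    spectra (MAF bins, Ti/Tv), haplogroup assignment on a user-supplied
    haplotree with Kulczynski set scoring, unsupervised sample
    classification (neighbor-joining phylogeny with Fitch parsimony
    scoring, PCA, UMAP), haploid linkage-disequilibrium structure with
    distance-matched nuclear comparison, mtDNA copy-number estimation
    from depth ratios, genome-wide mtDNA-nDNA and copy-number-nDNA
    association scans, haploid haplotype-copying imputation with info
    scores and masking cross-validation, and a mitochondrial PheWAS with
    rank-based inverse-normal transformation. Includes a synthetic
    cohort generator emulating non-recombining tree-structured mtDNA
    haplotypes, recombining nuclear haplotypes, depth summaries and
    phenotypes, so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    mclust,
    withr,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
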