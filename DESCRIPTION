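Package: wcms
Title: Whole-Cell MALDI-TOF Fingerprint Clustering and Ribosomal Protein
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bacterial typing from whole-cell MALDI-TOF mass
    spectra (WC-MS): Savitzky-Golay smoothing, morphological (top-hat)
    baseline subtraction, relative-intensity scaling and replicate
    averaging; peak picking, cross-spectrum peak matching within a maximum
    shift, and binarization (>5% relative intensity, m/z 3,500-20,000);
    binary-Pearson (phi) proximity matrices, UPGMA dendrograms with Newick
    export, novelty calling against a type-strain library at a 0.5
    similarity threshold, and a permutation Mantel test against external
    similarity matrices such as 16S rRNA pairwise identity. Also predicts
    theoretical average masses of ribosomal proteins with the N-terminal
    methionine-excision rule and modification hypotheses (methylation,
    acetylation, beta-methylthiolation), annotates observed peak lists, and
    generates synthetic multi-species spectral libraries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    ape,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cluster.R'
    'mass-constants.R'
    'peak-matrix.R'
    'pipeline.R'
    'preprocess.R'
    'protein-mass.R'
    'seq-compare.R'
    'spectra-io.R'
    'synthetic.R'
    'utils.R'
    'wcms-package.R'
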