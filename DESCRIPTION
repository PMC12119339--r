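Package: coopselex
Title: Detection of Transcription-Factor Pair Spacing Preferences and
    Composite Motifs from CAP-SELEX Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cooperative DNA binding of transcription
    factor (TF) pairs from consecutive affinity-purification SELEX
    (CAP-SELEX) and single-TF HT-SELEX sequencing data. Implements
    positional mutual information over paired 4-mer sets to detect spacing
    and orientation preferences between two TFs' binding sites; k-mer
    relative-affinity estimation against a fifth-order Markov background;
    composite-motif discovery by comparing pair versus single-TF affinity
    tables, with IUPAC seed refinement and multinomial position count
    matrix construction; motif-set reduction via minimum dominating sets;
    discovery-saturation estimation by subsampling; genomic motif scanning
    with hypergeometric region enrichment; conservation analysis of motif
    matches against recombined control motifs using Gaussian-mixture
    thresholding of per-base scores; and a thermodynamic SELEX simulator
    that plants monomer and cooperative dimer binding landscapes as ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
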