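Package: homeologr
Title: Subgenome Phasing and Homeolog Expression Analysis for Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying subgenome evolution in allopolyploids from
    long-read transcriptomes when no reference genome is available.
    Implements diagnostic-SNP phasing of full-length isoforms into parental
    subgenomes from one-to-one orthogroup alignments of diploid progenitors,
    tabulation of homeolog expression classes with saturation (rarefaction)
    modelling, Nei-Gojobori (1986) synonymous-substitution (Ks) estimation
    with Gaussian-mixture peak detection and divergence-time conversion,
    reference-free alternative-splicing detection against a merged-CDS
    orthogroup reference, VCF-based homeolog-specific expression and
    dominance analysis, bootstrap-screened gene-tree subgenome assignment,
    and flow-cytometry ploidy arithmetic. A synthetic allopolyploid
    transcriptome generator provides fully reproducible inputs for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
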