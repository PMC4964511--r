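Package: codonBias
Title: Codon Usage Bias Analysis for Coding Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-scale analysis of synonymous codon usage in
    coding sequences. Reads and quality-filters CDS FASTA files, computes
    nucleotide-composition indices (GC, GC1, GC2, GC3, GC12, GC3s and
    base-specific third-position fractions), relative synonymous codon usage
    (RSCU), Wright's effective number of codons (ENC), the codon adaptation
    index (CAI), GRAVY and aromaticity; draws the expected-ENC null curve and
    the GC12-on-GC3 neutrality regression; performs correspondence analysis
    of per-gene RSCU profiles; and determines optimal codons from the RSCU
    contrast between the most- and least-biased gene subsets ranked by ENC
    ratio. Includes a synthetic CDS generator with controllable mutational
    GC pressure and translational selection so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
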