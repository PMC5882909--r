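Package: camtakit
Title: Comparative Evolution and Regulatory Analysis of Plant CAMTA Gene Families
Version: 0.1.0
Authors@R:
    person("Plant Genomics", "Toolkit Authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-scale characterisation of calmodulin-binding
    transcription activator (CAMTA) gene families and their regulatory context:
    consensus-pattern scanning of CG-1, TIG, ankyrin, IQ and calmodulin-binding
    domains with protein property computation (length, molecular weight,
    isoelectric point, intron counts, hydrophobic moment), paralog and
    reciprocal-best-hit ortholog detection from pairwise alignments,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    selection-pressure labelling and molecular-clock duplication dating,
    segmental versus tandem duplication classification, neighbor-joining trees
    with bootstrap support, focal-gene co-expression networks from FPKM
    matrices, IUPAC degenerate cis-motif promoter enrichment with Fisher's
    exact test, qRT-PCR relative quantification (2^-ddCt) and expression-trait
    correlation. A seeded synthetic-data generator produces genomes, gene
    models, diverged codon pairs, promoter sets, expression matrices and trait
    tables with known ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
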