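Package: kuscape
Title: Phyletic Profiling of Classical NHEJ Loss and Lineage-Specific
    Protein Insertions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to profile the presence of the classical
    non-homologous end joining (C-NHEJ) components Ku70, Ku80 and DNA
    ligase IV across eukaryotic genomes, contrast genome sizes between
    pathway-lacking and pathway-bearing lineages, and count minimum
    independent pathway losses on a species tree by Dollo parsimony.
    Also detects lineage-specific insertion blocks in orthologous
    protein multiple sequence alignments, quantifies per-taxon
    insertion fractions, and provides amino-acid composition
    enrichment, flank-divergence, conservation and mass-spectrometry
    peptide-coverage statistics, plus simulators that generate both
    kinds of input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
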