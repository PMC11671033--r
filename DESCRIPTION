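Package: seqlensplit
Title: Split FASTA Files by Sequence Length with Plots and Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Splits a FASTA file of nucleotide or protein sequences into
    above-cutoff and below-cutoff files at a configurable length threshold
    (default 200), writes a statistical summary of sequence lengths (counts
    and minimum/maximum for the input and both partitions), and renders
    length-distribution histograms in linear and logarithmic scale as PNG
    files. Includes a command-line entry point and a seeded synthetic FASTA
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
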