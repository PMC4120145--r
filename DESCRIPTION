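Package: splicegraphr
Title: Splicing Graphs and De Novo Expression Estimates from De Bruijn
    Graphs of RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Postprocessing of de Bruijn graphs built from RNA-Seq reads
    into per-gene acyclic splicing graphs with base-precise junctions,
    without a reference genome.  Builds a bidirected double-stranded
    k-mer graph from FASTA/FASTQ libraries (or imports a Velvet
    LastGraph file), compacts unitigs, applies a k-mer coverage cutoff,
    clips short tips, merges SNP-induced split-then-merge bubbles,
    removes strongly connected components and forward-backward strand
    tangles, adjusts merge junctions to base precision, filters short
    assemblies, and reports per-node per-library RPKM expression
    estimates computed from reads appearing in the assembly.  Includes a
    transcript/read simulator with ground-truth splice junctions and a
    junction sensitivity/specificity evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
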