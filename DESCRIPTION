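Package: synmapr
Title: Comparative Genetic and Genomic Map Alignment, Conserved Synteny
    Discovery and Vertical Map Rendering
Version: 0.1.0
Authors@R:
    person("synmapr", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for loading genetic (cM) and genomic (bp) marker maps from
    plain-text, XML, GFF3 and BED files, relating markers across maps by
    identity (shared accession), synonymy (shared name) or gene homology
    (Compara-style orthology/paralogy tables with percent amino-acid
    identity/similarity scores), discovering regions of conserved synteny
    from a homology table, constructing in-silico PCR (ePCR) bridge maps
    from primer panels and genome FASTA files, laying maps out in virtual
    columns on a 2-D canvas, and rendering aligned vertical maps with typed,
    colour-blind-safe relationship lines to deterministic SVG.  A synthetic
    data generator produces genome pairs with implanted syntenic blocks,
    jittered linkage maps and primer-implanted genomes with known ground
    truth, so the whole pipeline is testable offline.  A command-line
    interface exposes conversion, link discovery, synteny search, ePCR
    mapping, simulation and drawing as scriptable subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
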