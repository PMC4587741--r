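Package: stitchmap
Title: Optical Genome Map Super-Scaffolding of Draft Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for super-scaffolding fragmented genome assemblies with
    single-molecule (optical) genome maps. Reads and writes the BNX, CMAP and
    XMAP text formats, digests sequence scaffolds into in silico label maps by
    nicking-enzyme motif search, rescales per-scan molecule stretch (bases per
    pixel) against in silico maps, plans and ranks consensus-map assembly
    parameter sweeps, and iteratively stitches sequence scaffolds into super
    scaffolds from consensus-map alignments, emitting FASTA and AGP 2.0 with
    estimated gap lengths and mis-assembly flags. Includes a synthetic-data
    generator and a naive overlap aligner so the whole pipeline can be
    exercised without proprietary assembly software.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
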