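Package: capsidlattice
Title: Icosahedral Capsid Architectures, Sub-Particle Geometry and Prophage
    Scanning for Pseudo-Hexameric Trimer Capsids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry and sequence analysis for icosahedral virus capsids
    built from pseudo-hexameric trimers of double jelly-roll major capsid
    proteins, such as the lipid-containing ssDNA phages of Flavobacterium.
    Provides the icosahedral rotation group with its symmetry-axis and orbit
    machinery; Caspar-Klug lattice construction, classification and a
    constraint analysis (trimer placement on two-fold axes, hexamer
    complexity) that enumerates the capsid architectures available to
    trimeric building blocks; pseudo-T=21 quasi-equivalence bookkeeping
    (trimer types, asymmetric-unit composition) and synthetic capsid point
    models; localized-reconstruction sub-particle geometry (symmetry
    expansion with special-position deduplication, local-axis alignment,
    defocus adjustment, C5 symmetry-relaxation candidates, composite
    stitching); prophage locus calling from homology hit tables with
    dif-site palindrome detection, sequence-logo matrices and per-residue
    conservation mapping onto structures; and seeded synthetic-data
    generators (particle tables, genomes with implanted prophage cassettes,
    mutated sequence families) for exercising every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
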