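Package: kelpRefugia
Title: COI Haplotype Networks and Glacial-Maximum Cover Hindcasts for Kelp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring evolutionary refugia in kelp populations.
    Implements a COI-barcode population-genetics workflow (alignment QC,
    degenerate-primer trimming, haplotype collapsing, nucleotide and
    haplotype diversity statistics, and statistical-parsimony haplotype
    networks with a 95 percent connection limit) together with a
    paleoclimate hindcast that projects kelp cover from mean annual sea
    surface temperature through a thermal response curve, masks habitat by
    depth band under a glacial sea-level offset, and summarises latitudinal
    range shifts. A synthetic-data module generates deterministic alignment
    fixtures and gridded temperature/bathymetry fields so the whole pipeline
    is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignio.R'
    'haplotypes.R'
    'diversity.R'
    'network.R'
    'paleocover.R'
    'synthetic.R'
    'pipeline.R'
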