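Package: capmapr
Title: Genotyping-by-Capture Simulation, SNP Filtering and RIL Linkage Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building dense genetic maps of selfed recombinant
    inbred line (RIL) populations genotyped by targeted sequence capture.
    Covers allele-specific 120-mer bait design from exon-annotated contigs
    (with a tandem-microsatellite screen), read-count based genotype calling
    with locus-level recovery accounting, a quality-filter cascade (Fis,
    completeness, Nei's expected heterozygosity, per-contig de-duplication),
    de novo linkage-group construction from two-point LOD scores with
    Haldane-Waddington correction for selfed lines, marker ordering by
    simulated annealing, and validation of the resulting map against
    putative physical and genetic positions.  A synthetic-data module
    simulates reference contigs, an F6 RIL population and capture coverage
    (bait-dose effects, capture failure, microsatellite sink contigs) so the
    whole pipeline can be exercised and property-tested without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
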