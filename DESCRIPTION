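Package: kmerphylo
Title: Alignment-Free k-mer Phylogenomics of Annotated Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free phylogenomic analysis of annotated genome
    assemblies based on k-mers. Curates region-specific sequence sets
    (whole genome, repeat-masked genome, CDS, introns, repeats, proteins)
    from FASTA plus GFF3 annotations, counts k-mers and optimises the word
    length k, computes the centred self-normalised D2S similarity statistic
    between genome pairs and transforms it into a bounded distance, infers
    neighbour-joining trees and thresholded genome-relatedness networks,
    compares topologies with a species-aware normalised Robinson-Foulds
    distance, identifies core k-mers conserved across genome groups and
    classifies them against annotated features, and screens repeat types
    for differential abundance and Kimura-divergence conservation between
    lifestyle groups. Includes a genome-collection simulator (Jukes-Cantor
    substitution along a species tree, gene and repeat-family models,
    planted conserved elements) so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core-kmers.R'
    'd2s.R'
    'feature-mapping.R'
    'io-sequences.R'
    'io-trees.R'
    'kmerphylo-package.R'
    'kmers.R'
    'network.R'
    'pipeline.R'
    'regions.R'
    'repeat-stats.R'
    'simulate.R'
    'tree.R'
    'utils.R'
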