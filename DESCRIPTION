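Package: sdrscan
Title: Sex-Determining Region Detection and Introgressed Y-Chromosome Analysis
    from Phased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genomic scans for locating a sex-determining
    region (SDR) from male/female genotype contrasts, splitting male
    haplotypes into X and Y gametologs by overlapping-window gene-tree voting,
    and testing whether a young Y chromosome originated by introgression from
    a sister species. Provides Hudson's Fst, nucleotide diversity, sex-limited
    SNP fractions, coverage ratios, ABBA-BABA D and the fd admixture-fraction
    estimator, quartet topology weighting, direction-of-introgression
    classification, dxy-based discrimination of introgression from incomplete
    lineage sorting, and Nei-Gojobori dN/dS. A coalescent window simulator
    with known truth (autosome, pseudoautosomal, and SDR genealogies under
    introgression and lineage-sorting scenarios) makes every stage testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    vcfR,
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
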