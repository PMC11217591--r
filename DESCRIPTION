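Package: paleometh
Title: Methylation Inference from Postmortem Damage in Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating relative CpG methylation from postmortem
    cytosine deamination in UDG-treated ancient shotgun genomes. Builds CpG
    catalogs with SNP masking and island/shore/shelf annotation, counts
    deaminated versus non-deaminated read evidence at CpG sites to form
    methylation scores, equalizes genomes to a common genome-wide mean score
    by Monte Carlo read subsampling, and runs gene-level differential
    methylation statistics (multistratum ANOVA on binary deamination,
    gene-averaged ANOVA/Kruskal-Wallis, multidimensional scaling, chromosome-X
    sex contrasts, and co-directionality against external differential
    methylation tables). Includes a full synthetic-cohort generator with
    truth ledgers so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    data.table,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
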