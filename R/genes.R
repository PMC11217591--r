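#' Build the two gene-level methylation datasets
#'
#' From the Monte Carlo normalized replicates, produces the two dataset
#' shapes downstream statistics use:
#'
#' * the full dataset: per replicate, per gene, one row per CpG site per
#'   genome with the subsampled counts (`n1`, `n0`) and site MS - the
#'   material for read-level multistratum models;
#' * the gene-averaged matrix: per gene and genome, the mean of its site MS
#'   values within a replicate, averaged across the replicates in which the
#'   cell exists.
#'
#' CpG-to-gene assignment uses overlap with the gene's exon-bounding span by
#' default (`exon_only = FALSE`); a site overlapping several genes is counted
#' in each. Replicate-level gene sets may differ because subsampling can
#' empty low-count sites.
#'
#' @param replicates List of replicate datasets (each a named list of
#'   per-genome site tables), as `make_replicates()$replicates`.
#' @param genes Gene interval table from [derive_gene_intervals()] (or any
#'   data.frame with `gene_id`, `chrom`, `start`, `end`).
#' @param exons Optional exon table; required when `exon_only = TRUE`.
#' @param exon_only Assign CpGs by exon overlap instead of gene span.
#' @return list with `full` (data.table: `replicate`, `gene_id`, `genome_id`,
#'   `chrom`, `pos`, `n1`, `n0`, `ms`), `matrix` (data.table: `gene_id` plus
#'   one mean-MS column per genome) and `n_cpg` (same shape, mean number of
#'   contributing CpGs per replicate).
#' @export
build_gene_datasets <- function(replicates, genes, exons = NULL,
                                exon_only = FALSE) {
  stopifnot(length(replicates) >= 1L)
  if (exon_only) {
    if (is.null(exons)) stop_contract("exon_only = TRUE requires the exon table")
    iv <- data.frame(gene_id = exons$gene_id, chrom = exons$chrom,
                     start = exons$exon_start, end = exons$exon_end)
  } else {
    iv <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  ggr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))

  full_l <- list()
  for (r in seq_along(replicates)) {
    rep_r <- replicates[[r]]
    dt <- data.table::rbindlist(lapply(names(rep_r), function(id) {
      x <- data.table::as.data.table(rep_r[[id]])[, c("chrom", "pos", "n1", "n0", "ms")]
      x$genome_id <- id
      x
    }))
    if (!nrow(dt)) next
    sgr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos + 1L, dt$pos + 1L))
    hits <- GenomicRanges::findOverlaps(sgr, ggr)
    if (!length(hits)) next
    out <- dt[S4Vectors::queryHits(hits), ]
    out$gene_id <- iv$gene_id[S4Vectors::subjectHits(hits)]
    out$replicate <- r
    full_l[[r]] <- out
  }
  if (!length(full_l))
    stop_contract("no genes overlap any CpG site in any replicate")
  full <- data.table::rbindlist(full_l)
  # exon-mode can assign a site to the same gene via several exons
  full <- unique(full, by = c("replicate", "gene_id", "genome_id", "chrom", "pos"))

  per_rep <- full[, list(ms = mean(ms), n_cpg = .N),
                  by = c("replicate", "gene_id", "genome_id")]
  cell <- per_rep[, list(ms = mean(ms), n_cpg = mean(n_cpg)),
                  by = c("gene_id", "genome_id")]
  mat <- data.table::dcast(cell, gene_id ~ genome_id, value.var = "ms")
  ncpg <- data.table::dcast(cell, gene_id ~ genome_id, value.var = "n_cpg")
  list(full = full, matrix = mat, n_cpg = ncpg)
}

#' Farmer-minus-hunter-gatherer methylation differences per gene
#'
#' From a gene-averaged matrix, the per-gene difference of mean MS between
#' the NF and HG genome groups (`deltaMS(F-HG)`), optionally restricted to a
#' genome subset (e.g. a single laboratory's genomes).
#'
#' @param gmatrix Gene-averaged matrix (`gene_id` + genome columns).
#' @param meta Cohort metadata.
#' @param genomes Optional subset of genome ids to use.
#' @return data.frame with `gene_id`, `delta` (mean NF - mean HG), `n_nf`,
#'   `n_hg`; genes lacking data in either group are dropped.
#' @export
delta_ms_by_gene <- function(gmatrix, meta, genomes = NULL) {
  gmatrix <- data.table::as.data.table(gmatrix)
  ids <- intersect(names(gmatrix), meta$genome_id)
  if (!is.null(genomes)) ids <- intersect(ids, genomes)
  grp <- meta$subsistence[match(ids, meta$genome_id)]
  nf <- ids[grp == "NF"]; hg <- ids[grp == "HG"]
  if (!length(nf) || !length(hg))
    stop_contract("both NF and HG genomes are required")
  m <- as.matrix(gmatrix[, ids, with = FALSE])
  mean_nf <- rowMeans(m[, nf, drop = FALSE], na.rm = TRUE)
  mean_hg <- rowMeans(m[, hg, drop = FALSE], na.rm = TRUE)
  out <- data.frame(gene_id = gmatrix$gene_id, delta = mean_nf - mean_hg,
                    n_nf = rowSums(!is.na(m[, nf, drop = FALSE])),
                    n_hg = rowSums(!is.na(m[, hg, drop = FALSE])))
  out[out$n_nf > 0 & out$n_hg > 0 & is.finite(out$delta), ]
}
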