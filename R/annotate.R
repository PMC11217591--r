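#' Catalog CpG positions of a reference with SNP masking
#'
#' Scans the requested chromosomes for CG dinucleotides and returns one
#' record per biological CpG site, keyed by the 0-based position of the C on
#' the forward strand (reverse-strand G evidence is folded onto the same key
#' by the scoring module). Sites overlapping the SNP exclusion mask are
#' removed so that genuine C/T variants cannot masquerade as deamination.
#'
#' @param bundle A `ref_bundle` (or any list with `seq` and `mask`).
#' @param chroms Chromosomes to scan. Default: all autosomes (every
#'   chromosome except `chrX`). Pass `"chrX"` for the chrX catalog.
#' @return data.table with `chrom`, `pos` (0-based C position) and
#'   `chrom_class` (`"autosome"`/`"chrX"`).
#' @export
catalog_cpgs <- function(bundle, chroms = NULL) {
  seq_set <- bundle$seq
  mask <- bundle$mask %||% GenomicRanges::GRanges()
  if (is.null(chroms)) chroms <- setdiff(names(seq_set), "chrX")
  if (!all(chroms %in% names(seq_set)))
    stop_contract("chromosome(s) absent from reference: ",
                  paste(setdiff(chroms, names(seq_set)), collapse = ", "))
  if (length(mask) &&
      !all(as.character(GenomeInfoDb::seqnames(mask)) %in% names(seq_set)))
    stop_contract("SNP mask names a chromosome absent from the reference")
  cat_dt <- data.table::as.data.table(cpg_positions(seq_set[chroms]))
  if (nrow(cat_dt) && length(mask)) {
    gr <- GenomicRanges::GRanges(cat_dt$chrom,
                                 IRanges::IRanges(cat_dt$pos + 1L, cat_dt$pos + 1L))
    cat_dt <- cat_dt[!IRanges::overlapsAny(gr, mask), ]
  }
  cat_dt$chrom_class <- ifelse(cat_dt$chrom == "chrX", "chrX", "autosome")
  data.table::setorderv(cat_dt, c("chrom", "pos"))
  cat_dt[]
}

#' Classify CpG sites into island / shore / shelf / open sea
#'
#' Assigns each catalog site a genomic-context class relative to the CpG
#' island track: `island` inside a (merged) CGI, `shore5`/`shore3` within
#' 2 kb up-/downstream of an island, `shelf5`/`shelf3` within the next 2 kb,
#' `open_sea` beyond. Where the flanks of adjacent islands overlap, the
#' nearer island assigns the tier (ties go to the upstream island's
#' downstream flank). The classes are mutually exclusive and exhaustive.
#'
#' @param sites Catalog data.table from [catalog_cpgs()].
#' @param cgi CGI track as a [GenomicRanges::GRanges] (overlapping intervals
#'   are merged before flanking).
#' @param tier_width Width of each flank tier in bp (2000).
#' @return The catalog with a `context` column added.
#' @export
classify_context <- function(sites, cgi, tier_width = 2000L) {
  sites <- data.table::as.data.table(sites)
  ctx <- rep("open_sea", nrow(sites))
  cgi <- GenomicRanges::reduce(cgi)
  for (ch in unique(sites$chrom)) {
    ii <- which(sites$chrom == ch)
    isl <- cgi[as.character(GenomeInfoDb::seqnames(cgi)) == ch]
    if (!length(isl)) next
    s <- BiocGenerics::start(isl) - 1L   # 0-based
    e <- BiocGenerics::end(isl)          # half-open end
    p <- sites$pos[ii]
    j <- findInterval(p, s)
    inside <- j >= 1L & p < e[pmax(j, 1L)]
    dist_left <- ifelse(j >= 1L, p - e[pmax(j, 1L)] + 1L, Inf)
    dist_right <- ifelse(j < length(s), s[pmin(j + 1L, length(s))] - p, Inf)
    use_left <- dist_left <= dist_right   # tie -> upstream island's 3' flank
    d <- ifelse(use_left, dist_left, dist_right)
    side <- ifelse(use_left, "3", "5")
    cls <- rep("open_sea", length(p))
    cls[d <= 2L * tier_width] <- paste0("shelf", side[d <= 2L * tier_width])
    cls[d <= tier_width] <- paste0("shore", side[d <= tier_width])
    cls[inside] <- "island"
    ctx[ii] <- cls
  }
  sites$context <- ctx
  sites[]
}

#' Derive gene spans and promoters from an exon table
#'
#' Collapses a UCSC-style exon table (0-based starts, 1-based ends, one row
#' per exon) into one record per gene: the bounding span of its exons and a
#' 4 kb promoter centered on the gene's 5'-most exon boundary - 2 kb upstream
#' plus 2 kb downstream of the first exon start for plus-strand genes,
#' mirrored around the last exon end for minus-strand genes, clipped at
#' chromosome bounds.
#'
#' @param exons Exon table (`gene_id`, `chrom`, `strand`, `exon_start`,
#'   `exon_end`).
#' @param chrom_lengths Optional named vector used to clip promoters on the
#'   right.
#' @param promoter_half Half-width of the promoter (2000).
#' @return data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `promoter_start`, `promoter_end` (all 0-based half-open).
#' @export
derive_gene_intervals <- function(exons, chrom_lengths = NULL,
                                  promoter_half = 2000L) {
  assert_columns(exons, c("gene_id", "chrom", "strand", "exon_start", "exon_end"))
  g <- gene_spans(exons)
  if (!nrow(g)) {
    g$promoter_start <- integer(0); g$promoter_end <- integer(0)
    return(g)
  }
  anchor <- ifelse(g$strand == "-", g$end, g$start)
  g$promoter_start <- pmax(0L, as.integer(anchor - promoter_half))
  g$promoter_end <- as.integer(anchor + promoter_half)
  if (!is.null(chrom_lengths)) {
    lim <- as.integer(chrom_lengths[g$chrom])
    g$promoter_end <- pmin(g$promoter_end, lim)
  }
  g
}

#' Write a CpG catalog as BED
#'
#' One BED line per site (width 1, the C position), with the context class in
#' the name column when present.
#'
#' @param sites Catalog (optionally context-classified).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(sites, path) {
  nm <- if ("context" %in% names(sites)) sites$context else "."
  df <- data.frame(sites$chrom, sites$pos, sites$pos + 1L, nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
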