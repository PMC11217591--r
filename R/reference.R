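#' Build a synthetic reference bundle
#'
#' Generates a miniature reference genome together with the annotation tracks
#' the downstream pipeline consumes: a CpG-island (CGI) track, a gene/exon
#' table and a SNP exclusion mask. Sequence composition is CpG-depleted
#' outside islands (roughly 1 percent of positions start a CG dinucleotide,
#' as in mammalian genomes) and CpG-enriched inside islands, so that the
#' island/shore/shelf/open-sea classifier has realistic material to work on.
#'
#' Islands are placed so that each island plus its 2 kb shores and 2 kb
#' shelves fits on its chromosome without overlapping the neighbouring
#' island's flanks. Genes are laid out on a disjoint grid; they may overlap
#' islands, as real genes do.
#'
#' @param n_chrom Number of autosomes to simulate.
#' @param chrom_length Length of every chromosome in bp.
#' @param n_islands Total number of CpG islands, distributed round-robin
#'   across chromosomes.
#' @param island_length Island width in bp.
#' @param n_genes Total number of genes, distributed round-robin across
#'   chromosomes (including chrX when present).
#' @param gene_span Genomic span of each gene in bp.
#' @param n_exons Exons per gene.
#' @param snp_fraction Fraction of CpG sites covered by the SNP mask.
#' @param include_chrx Add a chrX chromosome of the same length (genes and
#'   islands are placed on it like on autosomes).
#' @param island_cpg_spacing Distance between planted CG dinucleotides inside
#'   islands (bp).
#' @param cpg_keep_prob Retention probability of CG dinucleotides outside
#'   islands. The default 0.25 gives roughly 1 percent of positions starting
#'   a CpG (mammalian-like global depletion); raise it when gene bodies
#'   should carry realistic CpG counts (a few hundred per gene) on a
#'   miniature reference.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#'
#' @return An object of class `ref_bundle`: a list with elements `seq`
#'   (named [Biostrings::DNAStringSet]), `cgi` and `mask`
#'   ([GenomicRanges::GRanges], 0-based half-open when exported as BED),
#'   `exons` (data.frame with `gene_id`, `chrom`, `strand`, `exon_start`,
#'   `exon_end` in UCSC convention), `chrom_lengths` and `params`.
#' @export
build_reference <- function(n_chrom = 1L, chrom_length = 200000L,
                            n_islands = 5L, island_length = 1000L,
                            n_genes = 20L, gene_span = 5000L, n_exons = 3L,
                            snp_fraction = 0.01, include_chrx = FALSE,
                            island_cpg_spacing = 8L, cpg_keep_prob = 0.25,
                            seed = 1L) {
  stopifnot(n_chrom >= 1L, chrom_length >= 1000L, island_length >= 10L,
            snp_fraction >= 0, snp_fraction < 1)
  chroms <- paste0("chr", seq_len(n_chrom))
  if (include_chrx) chroms <- c(chroms, "chrX")
  nchr <- length(chroms)

  flank <- 4000L  # 2 kb shore + 2 kb shelf on each side
  isl_chr <- if (n_islands > 0) chroms[(seq_len(n_islands) - 1L) %% nchr + 1L] else character(0)
  gene_chr <- if (n_genes > 0) chroms[(seq_len(n_genes) - 1L) %% nchr + 1L] else character(0)
  # sizing checks: islands with full flanks must fit per chromosome
  for (ch in chroms) {
    k <- sum(isl_chr == ch)
    if (k > 0 && k * (island_length + 2L * flank) + 2L * flank > chrom_length)
      stop_contract("requested islands do not fit in chrom_length on ", ch)
    g <- sum(gene_chr == ch)
    if (g > 0 && g * (gene_span + 500L) > chrom_length)
      stop_contract("requested genes do not fit in chrom_length on ", ch)
  }

  with_seed(seed, {
    seqs <- character(nchr)
    cgi_dt <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      base <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3))
      # deplete CpGs: retain each CG dinucleotide with cpg_keep_prob
      cg <- which(base[-chrom_length] == "C" & base[-1L] == "G")
      if (length(cg)) {
        kill <- cg[stats::runif(length(cg)) > cpg_keep_prob]
        if (length(kill)) base[kill + 1L] <- "A"
      }
      # islands on this chromosome: evenly spaced, flanks inside bounds
      k <- sum(isl_chr == ch)
      if (k > 0) {
        slot <- (chrom_length - 2L * flank) / k
        starts <- as.integer(flank + (seq_len(k) - 1L) * slot +
                               (slot - island_length) / 2)
        for (s in starts) {
          at <- seq(s, s + island_length - 2L, by = island_cpg_spacing)
          base[at + 1L] <- "C"   # 1-based vector index for 0-based pos `at`
          base[at + 2L] <- "G"
        }
        cgi_dt[[length(cgi_dt) + 1L]] <-
          data.frame(chrom = ch, start = starts, end = starts + island_length)
      }
      seqs[ci] <- paste(base, collapse = "")
    }
    seq_set <- Biostrings::DNAStringSet(seqs)
    names(seq_set) <- chroms
    cgi_df <- if (length(cgi_dt)) do.call(rbind, cgi_dt) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    cgi <- GenomicRanges::GRanges(cgi_df$chrom,
                                  IRanges::IRanges(cgi_df$start + 1L, cgi_df$end))

    # gene/exon table (UCSC convention: 0-based start, end = half-open end)
    exon_rows <- list()
    if (n_genes > 0) {
      per_chr_idx <- stats::setNames(rep(0L, nchr), chroms)
      exon_len <- max(50L, min(200L, gene_span %/% (2L * n_exons)))
      for (gi in seq_len(n_genes)) {
        ch <- gene_chr[gi]
        per_chr_idx[ch] <- per_chr_idx[ch] + 1L
        slots <- sum(gene_chr == ch)
        slot <- chrom_length / slots
        s <- as.integer((per_chr_idx[ch] - 1L) * slot + (slot - gene_span) / 2)
        strand <- sample(c("+", "-"), 1L)
        if (n_exons == 1L) {
          starts <- s
        } else {
          inner <- sort(sample(seq(s + exon_len, s + gene_span - 2L * exon_len),
                               n_exons - 2L))
          starts <- c(s, inner, s + gene_span - exon_len)
        }
        exon_rows[[gi]] <- data.frame(
          gene_id = sprintf("G%03d", gi), chrom = ch, strand = strand,
          exon_start = starts, exon_end = starts + exon_len)
      }
    }
    exons <- if (length(exon_rows)) do.call(rbind, exon_rows) else
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), exon_start = integer(0),
                 exon_end = integer(0))

    # SNP mask over a random fraction of CpG C positions
    cg_pos <- cpg_positions(seq_set)
    n_mask <- round_half_up(nrow(cg_pos) * snp_fraction)
    mask <- if (n_mask > 0) {
      pick <- cg_pos[sample.int(nrow(cg_pos), n_mask), , drop = FALSE]
      GenomicRanges::GRanges(pick$chrom, IRanges::IRanges(pick$pos + 1L, pick$pos + 1L))
    } else GenomicRanges::GRanges()

    structure(list(
      seq = seq_set, cgi = sort(cgi), exons = exons, mask = sort(mask),
      chrom_lengths = stats::setNames(rep(chrom_length, nchr), chroms),
      params = list(n_chrom = n_chrom, chrom_length = chrom_length,
                    n_islands = n_islands, island_length = island_length,
                    n_genes = n_genes, gene_span = gene_span,
                    snp_fraction = snp_fraction, include_chrx = include_chrx,
                    seed = seed)),
      class = "ref_bundle")
  })
}

# All CG dinucleotide C positions (0-based) of a DNAStringSet.
cpg_positions <- function(seq_set) {
  out <- lapply(names(seq_set), function(ch) {
    hits <- Biostrings::matchPattern("CG", seq_set[[ch]])
    data.frame(chrom = ch, pos = BiocGenerics::start(hits) - 1L)
  })
  do.call(rbind, out)
}

#' Write a reference bundle to disk
#'
#' Writes `ref.fa` (+ `.fai` index), `cgi.bed`, `snp_mask.bed` (0-based
#' half-open BED) and `exons.tsv` under `dir`.
#'
#' @param bundle A `ref_bundle` from [build_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ref_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(bundle$seq, fa)
  Rsamtools::indexFa(fa)
  export_bed(bundle$cgi, file.path(dir, "cgi.bed"))
  export_bed(bundle$mask, file.path(dir, "snp_mask.bed"))
  utils::write.table(bundle$exons, file.path(dir, "exons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

export_bed <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a reference bundle back from disk
#'
#' Counterpart of [write_reference_bundle()].
#'
#' @param dir Directory containing `ref.fa`, `cgi.bed`, `snp_mask.bed`,
#'   `exons.tsv`.
#' @return A `ref_bundle`.
#' @export
read_reference_bundle <- function(dir) {
  fa <- file.path(dir, "ref.fa")
  seq_set <- Biostrings::readDNAStringSet(fa)
  names(seq_set) <- sub("\\s.*$", "", names(seq_set))
  read_bed <- function(p) {
    if (!file.size(p)) return(GenomicRanges::GRanges())
    gr <- rtracklayer::import.bed(p)
    S4Vectors::mcols(gr) <- NULL
    gr
  }
  exons <- utils::read.table(file.path(dir, "exons.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  structure(list(seq = seq_set,
                 cgi = read_bed(file.path(dir, "cgi.bed")),
                 exons = exons,
                 mask = read_bed(file.path(dir, "snp_mask.bed")),
                 chrom_lengths = stats::setNames(Biostrings::width(seq_set),
                                                 names(seq_set)),
                 params = list()),
            class = "ref_bundle")
}
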