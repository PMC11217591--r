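# Shared small fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fix_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- build_reference(n_chrom = 1L, chrom_length = 120000L,
                                        n_islands = 3L, island_length = 800L,
                                        n_genes = 10L, gene_span = 4000L,
                                        snp_fraction = 0.01, seed = 42L)
  .fixtures$bundle
}

fix_truth <- function() {
  if (is.null(.fixtures$truth))
    .fixtures$truth <- draw_truth_methylome(fix_bundle(), dmg_fraction = 0.2,
                                            seed = 43L)
  .fixtures$truth
}

fix_catalog <- function() {
  if (is.null(.fixtures$catalog))
    .fixtures$catalog <- classify_context(catalog_cpgs(fix_bundle()),
                                          fix_bundle()$cgi)
  .fixtures$catalog
}

# A ref_bundle wrapped around literal sequences, for hand-checked examples.
mini_bundle <- function(seqs, cgi = GenomicRanges::GRanges(),
                        mask = GenomicRanges::GRanges()) {
  ss <- Biostrings::DNAStringSet(seqs)
  structure(list(seq = ss, cgi = cgi,
                 exons = data.frame(gene_id = character(0), chrom = character(0),
                                    strand = character(0), exon_start = integer(0),
                                    exon_end = integer(0)),
                 mask = mask,
                 chrom_lengths = stats::setNames(Biostrings::width(ss), names(ss)),
                 params = list()),
            class = "ref_bundle")
}

# Manual read-table builder for scoring fixtures.
make_reads <- function(chrom, start, seq, strand = "+", mapq = 60L, nm = 0L) {
  n <- max(length(chrom), length(start), length(seq), length(strand))
  data.table::data.table(
    qname = paste0("r", seq_len(n)), chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + nchar(rep_len(seq, n))),
    strand = rep_len(strand, n), mapq = as.integer(rep_len(mapq, n)),
    nm = as.integer(rep_len(nm, n)), seq = rep_len(seq, n))
}

# Small cohort helpers used by several files.
fix_small_meta <- function(labs, n = 6L, seed = 3L) {
  cohort_metadata(n = n, n_hg = n %/% 2, n_female = n %/% 2,
                  n_tooth = n %/% 3, labs = labs, seed = seed)
}
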