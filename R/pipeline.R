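#' Simulate and score a whole synthetic cohort
#'
#' For each genome in the metadata sheet: simulate UDG-treated reads over
#' the reference, apply the read filters, count CpG evidence against the
#' catalog and apply the depth filter. Reads are discarded after scoring, so
#' arbitrarily large cohorts fit in memory; set `bam_dir` to also write each
#' genome's BAM, or `keep_ledgers = TRUE` to retain the truth ledgers for
#' oracle checks.
#'
#' @param bundle A `ref_bundle`.
#' @param truth A `truth_methylome`.
#' @param meta Cohort metadata ([cohort_metadata()]).
#' @param labs Lab profiles ([lab_profiles()]).
#' @param catalog CpG catalog to score against ([catalog_cpgs()]), or a named
#'   list of catalogs (e.g. autosomal and chrX) to score the same simulated
#'   reads against each; reads on chromosomes outside a catalog are ignored
#'   for that catalog.
#' @param damage_window Terminal damage/evidence window (bp), used for both
#'   simulation and scoring.
#' @param min_depth Depth filter ([apply_depth_filter()]).
#' @param seed Integer seed; per-genome seeds are derived from it.
#' @param bam_dir Optional directory to write per-genome BAMs.
#' @param keep_ledgers Retain per-genome truth ledgers in the result.
#' @return With a single catalog: list with `counts` (named list of
#'   depth-filtered site tables), `pooled` (data.frame of per-genome pooled
#'   mean MS and totals) and optionally `ledgers`. With a list of catalogs,
#'   `counts` and `pooled` are named lists with one entry per catalog.
#' @export
score_cohort <- function(bundle, truth, meta, labs, catalog,
                         damage_window = 20L, min_depth = 4L, seed = 1L,
                         bam_dir = NULL, keep_ledgers = FALSE) {
  check_meta(meta)
  single <- is.data.frame(catalog)
  catalogs <- if (single) list(all = catalog) else catalog
  stopifnot(length(catalogs) >= 1L, !is.null(names(catalogs)))
  empty <- stats::setNames(vector("list", nrow(meta)), meta$genome_id)
  counts <- lapply(catalogs, function(x) empty)
  ledgers <- if (keep_ledgers) empty else NULL
  pooled <- lapply(catalogs, function(x) list())
  if (!is.null(bam_dir)) dir.create(bam_dir, recursive = TRUE, showWarnings = FALSE)
  for (gi in seq_len(nrow(meta))) {
    row <- meta[gi, , drop = FALSE]
    sim <- simulate_genome_reads(bundle, truth, row, labs,
                                 damage_window = damage_window,
                                 seed = derive_seed(seed, gi))
    if (!is.null(bam_dir))
      write_genome_bam(sim$reads, bundle$chrom_lengths,
                       file.path(bam_dir, row$genome_id))
    reads <- filter_reads(sim$reads)
    for (cn in names(catalogs)) {
      cat_cn <- catalogs[[cn]]
      sub <- reads[reads$chrom %in% unique(cat_cn$chrom), ]
      cnt <- count_site_evidence(sub, cat_cn, row$library, damage_window)
      cnt <- apply_depth_filter(cnt, min_depth)
      counts[[cn]][[gi]] <- cnt
      pm <- if (nrow(cnt)) pool_mean_ms(cnt) else
        list(ms = NA_real_, N1 = 0L, N0 = 0L)
      pooled[[cn]][[gi]] <- data.frame(genome_id = row$genome_id, ms = pm$ms,
                                       N1 = pm$N1, N0 = pm$N0)
    }
    if (keep_ledgers) ledgers[[gi]] <- sim$ledger
  }
  pooled <- lapply(pooled, function(p) do.call(rbind, p))
  out <- if (single) list(counts = counts[[1L]], pooled = pooled[[1L]])
         else list(counts = counts, pooled = pooled)
  if (keep_ledgers) out$ledgers <- ledgers
  out
}

#' Pooled mean MS per genome of a count-table list
#'
#' @param count_list Named list of site-count tables.
#' @return Named numeric vector of pooled mean MS values.
#' @export
pooled_means <- function(count_list) {
  vapply(count_list, function(x) pool_mean_ms(x)$ms, numeric(1))
}

#' Write / read a per-genome site-count table
#'
#' TSV with columns `chrom`, `pos` (0-based C position), `n1`, `n0`, `ms`.
#'
#' @param counts Site-count table.
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_site_counts <- function(counts, path) {
  dt <- data.table::as.data.table(counts)
  if (!"ms" %in% names(dt)) dt$ms <- dt$n1 / (dt$n1 + dt$n0)
  data.table::fwrite(dt[, c("chrom", "pos", "n1", "n0", "ms")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Read an external differential-methylation table
#'
#' TSV with columns `gene`, `logFC`, `adj_p` (extra columns are kept).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_external_dmg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_columns(df, c("gene", "logFC"), "external table")
  df
}

#' Write an external differential-methylation table
#'
#' @param table data.frame with `gene`, `logFC`, `adj_p`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_external_dmg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
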