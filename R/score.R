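#' Filter aligned reads before methylation scoring
#'
#' Applies the standard aDNA quality filters: minimum read length 35 bp,
#' minimum mapping quality 30 and at most 10 percent mismatches to the
#' reference. Unmapped, secondary and duplicate alignments are assumed to
#' have been dropped at BAM load time ([read_genome_bam()] does so).
#'
#' @param reads Read table (`chrom`, `start`, `end`, `strand`, `mapq`, `nm`,
#'   `seq`).
#' @param min_length,min_mapq,max_mismatch_frac Filter thresholds.
#' @return The surviving reads.
#' @export
filter_reads <- function(reads, min_length = 35L, min_mapq = 30L,
                         max_mismatch_frac = 0.10) {
  reads <- data.table::as.data.table(reads)
  assert_columns(reads, c("chrom", "start", "end", "mapq"), "reads")
  len <- reads$end - reads$start
  if (is.null(reads$nm) || anyNA(reads$nm))
    stop_contract("mismatch count (NM) unavailable; provide reads with nm")
  keep <- len >= min_length & reads$mapq >= min_mapq &
    reads$nm / len <= max_mismatch_frac
  reads[keep, ]
}

#' Count deaminated versus non-deaminated evidence at CpG sites
#'
#' The core of damage-based methylation scoring. A filtered read contributes
#' to a catalog CpG site when the site's cytosine - the C at `pos` for
#' forward-orientation evidence, the G at `pos + 1` for reverse-orientation
#' evidence - lies within `damage_window` bases of an eligible read end: the
#' 5' end for double-stranded (`"ds"`) libraries, both ends for
#' single-stranded (`"ss"`). The observed base classifies the contribution:
#' T (A on the reverse orientation) is deaminated (`n1`), C (G) is
#' non-deaminated (`n0`), anything else contributes nothing. A read
#' contributes at most once per site; when both ends of an `ss` read are
#' eligible, the 5' end wins. The per-site methylation score is
#' `MS = n1 / (n0 + n1)`.
#'
#' @param reads Filtered read table.
#' @param catalog CpG catalog from [catalog_cpgs()].
#' @param library_type `"ds"` or `"ss"`.
#' @param damage_window Terminal window width in bp (default 20; match the
#'   window used when generating or modeling the data).
#' @return data.table with `chrom`, `pos`, `n1`, `n0`, `ms` for every catalog
#'   site with at least one contribution.
#' @export
count_site_evidence <- function(reads, catalog, library_type = c("ds", "ss"),
                                damage_window = 20L) {
  library_type <- match.arg(library_type)
  reads <- data.table::as.data.table(reads)
  catalog <- data.table::as.data.table(catalog)
  if (!nrow(reads))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  n1 = integer(0), n0 = integer(0),
                                  ms = numeric(0)))
  if (!all(unique(reads$chrom) %in% unique(catalog$chrom)))
    stop_contract("reads reference chromosome(s) absent from the catalog")
  W <- as.integer(damage_window)
  ss <- library_type == "ss"
  out <- list()
  for (ch in unique(reads$chrom)) {
    rr <- reads[reads$chrom == ch, ]
    cpos <- catalog$pos[catalog$chrom == ch]
    if (!length(cpos)) next
    L <- max(max(rr$end), max(cpos) + 2L)
    posC <- integer(L); posG <- integer(L)
    posC[cpos + 1L] <- seq_along(cpos)
    posG[cpos + 2L] <- seq_along(cpos)
    start <- rr$start; end <- rr$end; fwd <- rr$strand == "+"

    collect <- function(readix, five_prime, prio) {
      if (!length(readix)) return(NULL)
      rix <- rep(readix, each = W)
      off <- rep.int(seq_len(W) - 1L, length(readix))
      is_fwd <- fwd[readix[1L]]
      five_left <- xor(!five_prime, is_fwd)  # window at left end of alignment?
      p <- if (five_left) start[rix] + off else end[rix] - 1L - off
      site <- if (is_fwd) posC[p + 1L] else posG[p + 1L]
      keep <- site > 0L & p >= start[rix] & p < end[rix]
      if (!any(keep)) return(NULL)
      data.table::data.table(read = rix[keep], site = site[keep],
                             refpos = p[keep], prio = prio)
    }
    fr <- which(fwd); rv <- which(!fwd)
    pr <- list(collect(fr, TRUE, 1L), collect(rv, TRUE, 1L))
    if (ss) pr <- c(pr, list(collect(fr, FALSE, 2L), collect(rv, FALSE, 2L)))
    pairs <- data.table::rbindlist(pr[!vapply(pr, is.null, logical(1))])
    if (!nrow(pairs)) next
    data.table::setorderv(pairs, c("read", "site", "prio"))
    pairs <- pairs[!duplicated(pairs[, c("read", "site")]), ]
    o <- pairs$refpos - start[pairs$read] + 1L
    base <- substring(rr$seq[pairs$read], o, o)
    read_fwd <- fwd[pairs$read]
    n1 <- (read_fwd & base == "T") | (!read_fwd & base == "A")
    n0 <- (read_fwd & base == "C") | (!read_fwd & base == "G")
    keep <- n1 | n0
    if (!any(keep)) next
    out[[ch]] <- data.table::data.table(chrom = ch,
                                        pos = cpos[pairs$site[keep]],
                                        d = n1[keep])
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  n1 = integer(0), n0 = integer(0),
                                  ms = numeric(0)))
  ev <- data.table::rbindlist(out)
  counts <- ev[, list(n1 = sum(d), n0 = sum(!d)), by = c("chrom", "pos")]
  counts$ms <- counts$n1 / (counts$n1 + counts$n0)
  data.table::setorderv(counts, c("chrom", "pos"))
  counts[]
}

#' Score one genome from an indexed BAM
#'
#' Convenience wrapper: load the BAM, apply [filter_reads()], and run
#' [count_site_evidence()] against a catalog.
#'
#' @inheritParams count_site_evidence
#' @param bam Path to an indexed BAM.
#' @param ... Passed to [filter_reads()].
#' @return Per-site count table as from [count_site_evidence()].
#' @export
score_bam <- function(bam, catalog, library_type = c("ds", "ss"),
                      damage_window = 20L, ...) {
  reads <- filter_reads(read_genome_bam(bam), ...)
  count_site_evidence(reads, catalog, library_type, damage_window)
}

#' Apply the minimum-evidence depth filter
#'
#' Removes sites whose total evidence `n0 + n1` is below `min_depth`. The
#' conventional presets are 4 (`"default"`) and 10 (`"strict"`).
#'
#' @param counts Site-count table from [count_site_evidence()].
#' @param min_depth Minimum evidence reads per site; `"default"` = 4,
#'   `"strict"` = 10, or any integer >= 1.
#' @return Filtered site-count table.
#' @export
apply_depth_filter <- function(counts, min_depth = 4L) {
  if (is.character(min_depth))
    min_depth <- switch(min_depth, default = 4L, strict = 10L,
                        stop_contract("unknown depth preset: ", min_depth))
  stopifnot(min_depth >= 1L)
  counts <- data.table::as.data.table(counts)
  counts[(counts$n1 + counts$n0) >= min_depth, ]
}

#' Pooled mean methylation score of a site set
#'
#' Read-weighted pooled score `sum(n1) / (sum(n0) + sum(n1))` - the quantity
#' the Monte Carlo normalization equalizes across genomes - together with the
#' pooled totals.
#'
#' @param counts Site-count table.
#' @return list with `ms`, `N1`, `N0`.
#' @export
pool_mean_ms <- function(counts) {
  counts <- data.table::as.data.table(counts)
  if (!nrow(counts)) stop_contract("cannot pool an empty site set")
  N1 <- sum(counts$n1); N0 <- sum(counts$n0)
  list(ms = N1 / (N1 + N0), N1 = N1, N0 = N0)
}

#' Join per-genome site tables into a CpG x genome MS matrix
#'
#' Outer join on the site key; a cell is present iff that genome's site
#' passed the filters, otherwise `NA`.
#'
#' @param count_list Named list (genome id -> site-count table).
#' @return data.table with `chrom`, `pos` and one MS column per genome.
#' @export
assemble_matrix <- function(count_list) {
  stopifnot(length(count_list) >= 1L)
  ids <- names(count_list)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop_contract("count_list must be uniquely named by genome id")
  tabs <- lapply(ids, function(id) {
    dt <- data.table::as.data.table(count_list[[id]])[, c("chrom", "pos", "ms")]
    data.table::setnames(dt, "ms", id)
    dt
  })
  out <- Reduce(function(a, b) merge(a, b, by = c("chrom", "pos"), all = TRUE),
                tabs)
  data.table::setorderv(out, c("chrom", "pos"))
  out[]
}

#' Per-genome mean MS by genomic context, with island-contrast tests
#'
#' Computes, for each genome, the mean of site-level MS within each context
#' class (island, shores, shelves, open sea), and tests - across genomes,
#' paired - whether island MS is lower than each other class using a
#' one-sided Wilcoxon signed-rank test.
#'
#' @param count_list Named list of depth-filtered, context-annotated site
#'   tables (a `context` column, as after merging with a classified catalog).
#' @param contexts Optional catalog with `context` to annotate on the fly.
#' @return list with `summary` (data.table genome x context mean MS) and
#'   `tests` (data.frame context, p; island vs that context).
#' @export
context_summary <- function(count_list, contexts = NULL) {
  tabs <- lapply(names(count_list), function(id) {
    dt <- data.table::as.data.table(count_list[[id]])
    if (!"context" %in% names(dt)) {
      if (is.null(contexts))
        stop_contract("site tables lack a context column and no catalog given")
      dt <- merge(dt, data.table::as.data.table(contexts)[, c("chrom", "pos", "context")],
                  by = c("chrom", "pos"))
    }
    dt[, list(genome_id = id, mean_ms = mean(ms)), by = "context"]
  })
  summ <- data.table::rbindlist(tabs)
  wide <- data.table::dcast(summ, genome_id ~ context, value.var = "mean_ms")
  others <- setdiff(names(wide), c("genome_id", "island"))
  tests <- data.frame(context = others, p = NA_real_)
  if ("island" %in% names(wide)) {
    for (i in seq_along(others)) {
      x <- wide$island; y <- wide[[others[i]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) >= 2 && any(x[ok] != y[ok]))
        tests$p[i] <- stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                         alternative = "less", exact = FALSE)$p.value
      else if (sum(ok) >= 2)
        tests$p[i] <- 1
    }
  }
  list(summary = wide, tests = tests)
}
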