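#' Subsample one genome's reads to a target pooled mean MS
#'
#' Equalizes a genome's pooled mean methylation score to `target_ms` by
#' random subsampling without replacement, generalizing the factor
#' `(1 - t) / t` (49 at the conventional target t = 0.02):
#'
#' * case (a), original pooled MS below target: all deaminated reads are
#'   retained and `round((1 - t)/t * N1)` non-deaminated reads are drawn
#'   uniformly from the genome-wide non-deaminated pool;
#' * case (b), original pooled MS above target: all non-deaminated reads are
#'   retained and `round(N0 / ((1 - t)/t))` deaminated reads are drawn.
#'
#' Drawing uniformly over the genome-wide read pool allocates the retained
#' reads across sites as a multivariate hypergeometric. Rounding is half away
#' from zero, which minimizes the distance between the achieved and target
#' mean; the achieved pooled mean is always within one read of the target,
#' i.e. `|mean - t| <= 1/(retained total)`. Genomes already at the target
#' (within one read) are returned unchanged. Sites whose retained total
#' drops to zero are removed.
#'
#' @param counts Site-count table (`chrom`, `pos`, `n1`, `n0`), normally
#'   depth-filtered first.
#' @param target_ms Target pooled mean MS in (0, 1); default 0.02.
#' @param seed Integer seed.
#' @param genome_id Label used in error messages.
#' @return Site-count table with subsampled `n1`, `n0` (and `ms`), carrying
#'   attributes `achieved`, `case`, `N1s`, `N0s`.
#' @export
normalize_genome <- function(counts, target_ms = 0.02, seed = 1L,
                             genome_id = "genome") {
  stopifnot(target_ms > 0, target_ms < 1)
  counts <- data.table::as.data.table(counts)
  assert_columns(counts, c("chrom", "pos", "n1", "n0"), "counts")
  N1 <- sum(counts$n1); N0 <- sum(counts$n0)
  if (N1 + N0 == 0) stop_contract("no reads to normalize for ", genome_id)
  ratio <- (1 - target_ms) / target_ms
  ms0 <- N1 / (N1 + N0)

  with_seed(seed, {
    if (abs(N1 - target_ms * (N1 + N0)) < 1) {
      res <- counts; case <- "identity"
    } else if (ms0 < target_ms) {
      K0 <- as.integer(round_half_up(ratio * N1))
      if (N1 == 0L)
        stop_contract("cannot reach target MS for ", genome_id,
                      ": no deaminated reads")
      res <- data.table::copy(counts)
      res$n0 <- subsample_pool_counts(counts$n0, K0)
      case <- "a"
    } else {
      K1 <- as.integer(round_half_up(N0 / ratio))
      if (N0 == 0L)
        stop_contract("cannot reach target MS for ", genome_id,
                      ": no non-deaminated reads")
      res <- data.table::copy(counts)
      res$n1 <- subsample_pool_counts(counts$n1, K1)
      case <- "b"
    }
    res <- res[res$n1 + res$n0 > 0L, ]
    res$ms <- res$n1 / (res$n1 + res$n0)
    N1s <- sum(res$n1); N0s <- sum(res$n0)
    data.table::setattr(res, "achieved", N1s / (N1s + N0s))
    data.table::setattr(res, "case", case)
    data.table::setattr(res, "N1s", N1s)
    data.table::setattr(res, "N0s", N0s)
    res[]
  })
}

#' Build independent Monte Carlo normalized replicate datasets
#'
#' Applies [normalize_genome()] to every genome `R` times with
#' deterministically derived sub-seeds, producing `R` independent normalized
#' datasets. Normalization uses all of each genome's (depth-filtered) reads
#' genome-wide, not only gene-overlapping ones. Because low-count sites can
#' lose all reads in a draw, the surviving site (and downstream gene) sets
#' differ slightly between replicates; no depth re-filtering is applied after
#' subsampling.
#'
#' @param count_list Named list (genome id -> depth-filtered site table).
#' @param target_ms Target pooled mean MS; default 0.02.
#' @param R Number of replicates; the conventional choice is 20.
#' @param base_seed Integer seed from which replicate seeds are derived.
#' @return list with `replicates` (list of length `R`; each a named list of
#'   per-genome subsampled tables) and `manifest` (data.frame: replicate,
#'   genome, case, retained totals, achieved mean, seed).
#' @export
make_replicates <- function(count_list, target_ms = 0.02, R = 20L,
                            base_seed = 1L) {
  stopifnot(R >= 1L, length(count_list) >= 1L)
  ids <- names(count_list)
  manifest <- list()
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    one <- vector("list", length(ids)); names(one) <- ids
    for (gi in seq_along(ids)) {
      sd <- derive_seed(base_seed, (r - 1L) * length(ids) + gi)
      one[[gi]] <- normalize_genome(count_list[[gi]], target_ms, seed = sd,
                                    genome_id = ids[gi])
      manifest[[length(manifest) + 1L]] <- data.frame(
        replicate = r, genome_id = ids[gi],
        case = attr(one[[gi]], "case"),
        N1s = attr(one[[gi]], "N1s"), N0s = attr(one[[gi]], "N0s"),
        achieved = attr(one[[gi]], "achieved"), seed = sd)
    }
    reps[[r]] <- one
  }
  list(replicates = reps, manifest = do.call(rbind, manifest))
}

#' Build chrX replicate datasets scaled by the autosomal normalization
#'
#' The chrX analysis asks whether a genome's chrX methylation is elevated
#' relative to its autosomes, so chrX reads are subsampled with the same
#' case and retention fraction that the Monte Carlo normalization applies to
#' that genome's autosomes (rather than being forced to the fixed target
#' themselves, which would erase any chrX-specific signal). The retention
#' fraction is a deterministic function of the autosomal pooled totals;
#' only the allocation of retained chrX reads across sites is random.
#' Dividing the resulting chrX MS values by the genome's normalized
#' autosomal mean (see [normalize_chrx()]) then reproduces the raw
#' chrX-over-autosome ratio on a common scale.
#'
#' @param chrx_list Named list (genome id -> depth-filtered chrX site table).
#' @param auto_list Named list of the same genomes' autosomal site tables
#'   (used only for their pooled totals).
#' @param target_ms Autosomal normalization target; default 0.02.
#' @param R Number of replicates.
#' @param base_seed Integer seed.
#' @return list with `replicates` (as in [make_replicates()]) and `manifest`
#'   (per replicate and genome: case, fraction applied, achieved autosomal
#'   mean to divide by).
#' @export
make_chrx_replicates <- function(chrx_list, auto_list, target_ms = 0.02,
                                 R = 20L, base_seed = 1L) {
  ids <- names(chrx_list)
  stopifnot(all(ids %in% names(auto_list)))
  ratio <- (1 - target_ms) / target_ms
  plan <- lapply(ids, function(id) {
    a <- auto_list[[id]]
    N1 <- sum(a$n1); N0 <- sum(a$n0)
    if (N1 + N0 == 0) stop_contract("no autosomal reads for ", id)
    if (abs(N1 - target_ms * (N1 + N0)) < 1)
      list(case = "identity", side = NA, frac = 1,
           achieved = N1 / (N1 + N0))
    else if (N1 / (N1 + N0) < target_ms) {
      K0 <- round_half_up(ratio * N1)
      list(case = "a", side = "n0", frac = K0 / N0,
           achieved = N1 / (N1 + K0))
    } else {
      K1 <- round_half_up(N0 / ratio)
      list(case = "b", side = "n1", frac = K1 / N1,
           achieved = K1 / (K1 + N0))
    }
  })
  names(plan) <- ids
  reps <- vector("list", R); manifest <- list()
  for (r in seq_len(R)) {
    one <- stats::setNames(vector("list", length(ids)), ids)
    for (gi in seq_along(ids)) {
      id <- ids[gi]; pl <- plan[[id]]
      x <- data.table::copy(data.table::as.data.table(chrx_list[[id]]))
      sd <- derive_seed(base_seed + 31L, (r - 1L) * length(ids) + gi)
      if (pl$case != "identity") {
        side <- pl$side
        total <- sum(x[[side]])
        K <- min(total, as.integer(round_half_up(pl$frac * total)))
        x[[side]] <- with_seed(sd, subsample_pool_counts(x[[side]], K))
      }
      x <- x[x$n1 + x$n0 > 0L, ]
      x$ms <- x$n1 / (x$n1 + x$n0)
      one[[gi]] <- x
      manifest[[length(manifest) + 1L]] <- data.frame(
        replicate = r, genome_id = id, case = pl$case, fraction = pl$frac,
        achieved_auto = pl$achieved, seed = sd)
    }
    reps[[r]] <- one
  }
  list(replicates = reps, manifest = do.call(rbind, manifest))
}

# draw keep_total of sum(n_site) pooled reads uniformly without replacement;
# per-site retained counts (multivariate hypergeometric)
subsample_pool_counts <- function(n_site, keep_total) {
  total <- sum(n_site)
  if (keep_total >= total) return(n_site)
  picked <- sample.int(total, keep_total)
  cs <- cumsum(n_site)
  site_of <- findInterval(picked - 1L, c(0L, cs))
  tabulate(site_of, nbins = length(n_site))
}

#' Normalize chrX methylation scores by the autosomal mean
#'
#' Divides chrX MS values (site- or gene-level) by the same genome's pooled
#' autosomal mean MS, yielding the scale on which female/male chrX
#' methylation is compared.
#'
#' @param chrx_values data.frame/data.table with a `genome_id` column and a
#'   `ms` column of chrX MS values (any number of rows per genome).
#' @param autosomal_means Named numeric vector: genome id -> pooled autosomal
#'   mean MS (all must be > 0).
#' @return The input with a `ratio` column (`ms` / autosomal mean) added.
#' @export
normalize_chrx <- function(chrx_values, autosomal_means) {
  dt <- data.table::as.data.table(chrx_values)
  assert_columns(dt, c("genome_id", "ms"), "chrx_values")
  am <- autosomal_means[dt$genome_id]
  if (anyNA(am))
    stop_contract("missing autosomal mean for genome(s): ",
                  paste(unique(dt$genome_id[is.na(am)]), collapse = ", "))
  if (any(am <= 0))
    stop_contract("autosomal mean MS must be positive for every genome")
  dt$ratio <- dt$ms / as.numeric(am)
  dt[]
}
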