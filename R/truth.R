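#' Draw a ground-truth methylome over a reference bundle
#'
#' Assigns every CpG site of the reference a true methylation probability
#' `m`, drawn from context-specific Beta distributions: island sites are
#' hypomethylated (default mean 0.1), non-island sites are hypermethylated
#' (default mean 0.8), matching the classical genome-wide picture of 60-80
#' percent methylation outside hypomethylated CpG islands. A configurable
#' fraction of genes ("true DMGs") additionally carries a subsistence-group
#' effect: an additive shift `delta_m` applied to the farmer (NF) group's
#' CpGs within the gene span, clamped so that `m` stays in [0, 1].
#'
#' By default the shift is applied as NF hypomethylation (`effect_sign = -1`).
#' With the hypermethylated non-island baseline near 0.8, a positive shift of
#' the default magnitude would be mostly absorbed by the clamp at 1 and the
#' nominal effect size would be unattainable; a downward shift expresses the
#' full magnitude. Set `effect_sign = 0` for random signs per gene.
#'
#' @param bundle A `ref_bundle` from [build_reference()].
#' @param island_mean,opensea_mean Mean true methylation inside/outside
#'   islands, in (0, 1).
#' @param dmg_fraction Fraction of genes carrying a subsistence effect; the
#'   DMG count is `round(n_genes * dmg_fraction)`.
#' @param effect_size Absolute additive shift `|delta_m|` applied to NF CpGs
#'   of true DMGs.
#' @param effect_sign -1 (NF hypomethylation, default), +1, or 0 for a random
#'   sign per gene.
#' @param concentration Beta concentration (shape1 + shape2) of the per-site
#'   distributions; 10 gives Beta(1,9)/Beta(8,2) at the default means.
#' @param chrx_female_factor Multiplier applied to chrX site methylation in
#'   XX genomes at simulation time (X-inactivation-driven hypermethylation);
#'   1 disables the sex effect.
#' @param seed Integer seed.
#'
#' @return An object of class `truth_methylome`: list with `sites`
#'   (data.table `chrom`, `pos`, `island`, `m`, `m_nf`), `dmg` (data.table
#'   `gene_id`, `delta`), `genes` (gene spans used for effect placement) and
#'   `params`.
#' @export
draw_truth_methylome <- function(bundle, island_mean = 0.1, opensea_mean = 0.8,
                                 dmg_fraction = 0, effect_size = 0.5,
                                 effect_sign = -1, concentration = 10,
                                 chrx_female_factor = 1, seed = 1L) {
  stopifnot(inherits(bundle, "ref_bundle"),
            island_mean > 0, island_mean < 1,
            opensea_mean > 0, opensea_mean < 1,
            dmg_fraction >= 0, dmg_fraction <= 1)
  sites <- data.table::as.data.table(cpg_positions(bundle$seq))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  sites$island <- IRanges::overlapsAny(gr, bundle$cgi)
  genes <- gene_spans(bundle$exons)

  with_seed(seed, {
    n <- nrow(sites)
    m <- numeric(n)
    isl <- sites$island
    m[isl] <- stats::rbeta(sum(isl), concentration * island_mean,
                           concentration * (1 - island_mean))
    m[!isl] <- stats::rbeta(sum(!isl), concentration * opensea_mean,
                            concentration * (1 - opensea_mean))
    sites$m <- clamp01(m)

    n_dmg <- round_half_up(nrow(genes) * dmg_fraction)
    if (n_dmg > 0) {
      pick <- sample(genes$gene_id, n_dmg)
      sign_vec <- if (effect_sign == 0) sample(c(-1, 1), n_dmg, replace = TRUE)
                  else rep(effect_sign, n_dmg)
      dmg <- data.table::data.table(gene_id = pick, delta = sign_vec * effect_size)
    } else {
      dmg <- data.table::data.table(gene_id = character(0), delta = numeric(0))
    }

    # NF-group methylation: first covering DMG (if any) shifts the site
    sites$m_nf <- sites$m
    if (nrow(dmg)) {
      gd <- merge(genes, dmg, by = "gene_id")
      ggr <- GenomicRanges::GRanges(gd$chrom,
                                    IRanges::IRanges(gd$start + 1L, gd$end))
      hit <- GenomicRanges::findOverlaps(gr, ggr, select = "first")
      has <- !is.na(hit)
      sites$m_nf[has] <- clamp01(sites$m[has] + gd$delta[hit[has]])
    }

    structure(list(sites = sites, dmg = dmg, genes = genes,
                   params = list(island_mean = island_mean,
                                 opensea_mean = opensea_mean,
                                 dmg_fraction = dmg_fraction,
                                 effect_size = effect_size,
                                 effect_sign = effect_sign,
                                 concentration = concentration,
                                 chrx_female_factor = chrx_female_factor,
                                 seed = seed)),
              class = "truth_methylome")
  })
}

# Bounding span of each gene's exons (0-based half-open).
gene_spans <- function(exons) {
  if (!nrow(exons))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0), end = integer(0)))
  dt <- data.table::as.data.table(exons)
  out <- dt[, {
    if (length(unique(chrom)) > 1L)
      stop_contract("gene ", gene_id[1], " has exons on multiple chromosomes")
    list(chrom = chrom[1], strand = strand[1],
         start = min(exon_start), end = max(exon_end))
  }, by = "gene_id"]
  as.data.frame(out)
}

#' Generate an external differential-methylation table
#'
#' Emulates a published modern-cohort differential-methylation results file
#' (gene id, log fold-change, multiple-testing-adjusted p) to compare against
#' ancient farmer-versus-hunter-gatherer methylation differences. In
#' `"shared"` mode the logFC values are co-directional with the simulated
#' NF-HG effects plus Gaussian noise; in `"independent"` mode the same
#' marginal logFC distribution is assigned to genes independently of the
#' truth (effects permuted over genes), so the expected rank correlation with
#' the truth is zero.
#'
#' @param truth A `truth_methylome`.
#' @param overlap_mode `"shared"` or `"independent"`.
#' @param noise_sd Gaussian noise added to the logFC values.
#' @param seed Integer seed.
#' @return data.frame with columns `gene`, `logFC`, `adj_p`.
#' @export
make_external_dmg_table <- function(truth, overlap_mode = c("shared", "independent"),
                                    noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "truth_methylome"))
  overlap_mode <- match.arg(overlap_mode)
  genes <- truth$genes$gene_id
  eff <- stats::setNames(rep(0, length(genes)), genes)
  if (nrow(truth$dmg)) eff[truth$dmg$gene_id] <- truth$dmg$delta
  with_seed(seed, {
    base <- if (overlap_mode == "shared") as.numeric(eff) else
      as.numeric(eff)[sample.int(length(eff))]
    logFC <- base + stats::rnorm(length(genes), 0, noise_sd)
    scale <- max(noise_sd, 0.01)
    adj_p <- pmin(1, 2 * stats::pnorm(-abs(logFC) / scale))
    data.frame(gene = genes, logFC = logFC, adj_p = adj_p,
               stringsAsFactors = FALSE)
  })
}
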