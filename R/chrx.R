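#' Test chrX genes for sex-differential methylation
#'
#' Runs the chrX sex analysis on the full chrX gene dataset: site-level chrX
#' MS values are first normalized by each genome's pooled autosomal mean MS
#' (see [normalize_chrx()]), then every chrX gene is tested for a sex effect
#' with a stratified ANOVA (`ratio ~ sex + Error(stratum)`), using either
#' `individual` or `laboratory` as the error stratum; p-values are BH-
#' corrected per model and replicate. Per-sex distribution summaries of the
#' normalized values accompany the tests.
#'
#' @param chrx_full Full gene dataset built from chrX replicates
#'   (`build_gene_datasets()$full` over the chrX catalog).
#' @param meta Cohort metadata (must contain both sexes).
#' @param autosomal_means Named vector: genome id -> pooled autosomal mean
#'   MS.
#' @param models Error strata to run.
#' @param alpha BH threshold used in the returned significant counts.
#' @return list with `results` (data.table: replicate, gene_id, model, p,
#'   p_adj), `summary` (significant counts per model and replicate),
#'   `by_genome` (per replicate and genome: mean normalized chrX MS and sex)
#'   and `by_sex` (per replicate and sex: the median and mean of the
#'   per-genome means, plus the site-level mean).
#' @export
chrx_sex_test <- function(chrx_full, meta, autosomal_means,
                          models = c("individual", "laboratory"),
                          alpha = 0.05) {
  if (length(unique(meta$sex)) < 2L)
    stop_contract("chrX sex test requires both sexes in the cohort")
  full <- data.table::as.data.table(chrx_full)
  full <- normalize_chrx(full, autosomal_means)
  mi <- match(full$genome_id, meta$genome_id)
  full$sex <- meta$sex[mi]; full$lab <- meta$lab[mi]

  res_l <- list()
  for (r in sort(unique(full$replicate))) {
    fr <- full[full$replicate == r, ]
    genes <- unique(fr$gene_id)
    for (mod in models) {
      strat <- if (mod == "individual") "genome_id" else "lab"
      p <- vapply(genes, function(g) {
        d <- fr[fr$gene_id == g, ]
        if (length(unique(d$sex)) < 2L || length(unique(d[[strat]])) < 2L)
          return(NA_real_)
        if (stats::var(d$ratio) == 0) return(1)
        df <- data.frame(y = d$ratio, sex = factor(d$sex),
                         stratum = factor(d[[strat]]))
        fit <- tryCatch(suppressWarnings(
          stats::aov(y ~ sex + Error(stratum), data = df)),
          error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        unname(extract_stratum_p(fit, "sex"))
      }, numeric(1))
      res_l[[length(res_l) + 1L]] <- data.table::data.table(
        replicate = r, gene_id = genes, model = mod, p = p,
        p_adj = stats::p.adjust(p, method = "BH"))
    }
  }
  results <- data.table::rbindlist(res_l)
  summ <- results[!is.na(results$p_adj),
                  list(n_tested = .N, n_sig = sum(p_adj < alpha)),
                  by = c("model", "replicate")]
  by_genome <- full[, list(mean_ratio = mean(ratio), sex = sex[1L]),
                    by = c("replicate", "genome_id")]
  by_sex <- by_genome[, list(median_ratio = stats::median(mean_ratio),
                             mean_ratio = mean(mean_ratio)),
                      by = c("replicate", "sex")]
  list(results = results, summary = summ, by_genome = by_genome,
       by_sex = by_sex)
}
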