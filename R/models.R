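#' Multistratum ANOVA on read-level binary deamination for one gene
#'
#' Fits the read-level model
#' `deamination ~ subsistence + tissue + sex + Error(stratum)` for one gene,
#' where `deamination` is the binary per-read response (1 = deaminated) and
#' the error stratum is either `individual` (each genome its own stratum
#' unit) or `laboratory` (laboratory-of-origin). Sums of squares are
#' sequential (Type I) in the stated factor order; each fixed factor is
#' tested against the residual mean square of the stratum in which it
#' carries its degrees of freedom (for the individual stratum this is the
#' between-genome error, which is what protects the test - partially -
#' against read-level pseudoreplication).
#'
#' Genes where a factor has fewer than two levels among the genomes carrying
#' data, where the response is constant, or where a stratum has no residual
#' degrees of freedom are inestimable: the affected p-values are `NA`, not
#' errors.
#'
#' @param gene_dt Rows of the full gene dataset for one gene (and one
#'   replicate): columns `genome_id`, `n1`, `n0`.
#' @param meta Cohort metadata.
#' @param stratum `"individual"` or `"laboratory"`.
#' @param factors Fixed factors, in testing order.
#' @return Named numeric vector of p-values, one per factor (`NA` where
#'   inestimable).
#' @export
fit_stratified_model <- function(gene_dt, meta,
                                 stratum = c("individual", "laboratory"),
                                 factors = c("subsistence", "tissue", "sex")) {
  stratum <- match.arg(stratum)
  dat <- expand_deamination(gene_dt, meta)
  p_out <- stats::setNames(rep(NA_real_, length(factors)), factors)
  if (is.null(dat)) return(p_out)
  for (f in factors) if (length(unique(dat[[f]])) < 2L) return(p_out)
  if (length(unique(dat$y)) < 2L) return(p_out)
  strat_var <- if (stratum == "individual") "individual" else "laboratory"
  if (length(unique(dat[[strat_var]])) < 2L) return(p_out)
  fml <- stats::as.formula(paste("y ~", paste(factors, collapse = " + "),
                                 "+ Error(", strat_var, ")"))
  fit <- tryCatch(suppressWarnings(stats::aov(fml, data = dat)),
                  error = function(e) NULL)
  if (is.null(fit)) return(p_out)
  extract_stratum_p(fit, factors)
}

# Expand per-genome (n1, n0) counts into read-level binary rows joined with
# the genome's factor labels. Returns NULL when there is nothing to fit.
expand_deamination <- function(gene_dt, meta) {
  gene_dt <- data.table::as.data.table(gene_dt)
  agg <- gene_dt[, list(n1 = sum(n1), n0 = sum(n0)), by = "genome_id"]
  if (!all(agg$genome_id %in% meta$genome_id))
    stop_contract("genome(s) in gene data missing from metadata")
  tot <- agg$n1 + agg$n0
  agg <- agg[tot > 0L, ]; tot <- tot[tot > 0L]
  if (!nrow(agg)) return(NULL)
  mi <- match(agg$genome_id, meta$genome_id)
  y <- unlist(lapply(seq_len(nrow(agg)), function(i)
    rep(c(1L, 0L), c(agg$n1[i], agg$n0[i]))), use.names = FALSE)
  rows <- rep(seq_len(nrow(agg)), tot)
  data.frame(y = y,
             subsistence = factor(meta$subsistence[mi][rows]),
             tissue = factor(meta$tissue[mi][rows]),
             sex = factor(meta$sex[mi][rows]),
             individual = factor(agg$genome_id[rows]),
             laboratory = factor(meta$lab[mi][rows]))
}

# Per factor, take the p-value from the stratum where the factor carries the
# most degrees of freedom (its estimation stratum).
extract_stratum_p <- function(fit, factors) {
  s <- summary(fit)
  p_out <- stats::setNames(rep(NA_real_, length(factors)), factors)
  df_best <- stats::setNames(rep(-1, length(factors)), factors)
  for (str in s) {
    tab <- if (is.list(str)) str[[1L]] else str
    rn <- trimws(rownames(tab))
    if (!"Pr(>F)" %in% colnames(tab)) next
    for (f in factors) {
      i <- match(f, rn)
      if (!is.na(i) && tab$Df[i] > df_best[f] && !is.na(tab$`Pr(>F)`[i])) {
        df_best[f] <- tab$Df[i]
        p_out[f] <- tab$`Pr(>F)`[i]
      }
    }
  }
  p_out
}

#' Run the multistratum model battery over all genes and replicates
#'
#' Fits both stratified models (individual- and laboratory-stratum) for every
#' gene of every replicate of the full dataset, and applies Benjamini-
#' Hochberg correction per (model, factor, replicate) across the genes
#' tested there.
#'
#' @param full Full gene dataset (`build_gene_datasets()$full`).
#' @param meta Cohort metadata.
#' @param alpha Significance threshold applied to BH-adjusted p-values.
#' @param models Which error strata to run.
#' @param factors Fixed factors, in testing order.
#' @return list with `results` (data.table: replicate, gene_id, model,
#'   factor, p, p_adj) and `summary` (per model x factor: per-replicate
#'   significant-gene counts, their range, union and intersection sizes).
#' @export
run_model_battery <- function(full, meta, alpha = 0.05,
                              models = c("individual", "laboratory"),
                              factors = c("subsistence", "tissue", "sex")) {
  full <- data.table::as.data.table(full)
  res_l <- list()
  for (r in sort(unique(full$replicate))) {
    fr <- full[full$replicate == r, ]
    genes <- unique(fr$gene_id)
    for (mod in models) {
      ps <- lapply(genes, function(g)
        fit_stratified_model(fr[fr$gene_id == g, ], meta, mod, factors))
      pm <- do.call(rbind, ps)
      for (f in factors) {
        p <- pm[, f]
        res_l[[length(res_l) + 1L]] <- data.table::data.table(
          replicate = r, gene_id = genes, model = mod, factor = f,
          p = p, p_adj = stats::p.adjust(p, method = "BH"))
      }
    }
  }
  results <- data.table::rbindlist(res_l)
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, ]
  summ <- results[!is.na(results$p_adj),
                  list(n_tested = .N,
                       n_sig = sum(p_adj < alpha)),
                  by = c("model", "factor", "replicate")]
  agg <- summ[, list(min_sig = min(n_sig), max_sig = max(n_sig),
                     mean_frac = mean(n_sig / pmax(n_tested, 1L))),
              by = c("model", "factor")]
  sets <- lapply(split(sig, paste(sig$model, sig$factor)), function(x)
    split(x$gene_id, x$replicate))
  list(results = results, per_replicate = summ, summary = agg,
       significant_sets = sets)
}

#' Gene-averaged ANOVA and Kruskal-Wallis tests
#'
#' One-factor-at-a-time tests on the gene-averaged matrix: per gene with at
#' least `min_individuals` non-missing cells and at least two factor levels
#' represented, a one-way ANOVA F-test and a Kruskal-Wallis test of the cell
#' values grouped by the factor, BH-corrected across genes. One observation
#' per genome per gene, so there is no read-level pseudoreplication.
#'
#' @param gmatrix Gene-averaged matrix (`gene_id` + genome columns).
#' @param meta Cohort metadata.
#' @param factor_name One of `subsistence`, `tissue`, `sex`, `lab`.
#' @param min_individuals Minimum non-missing genomes per gene; conventional
#'   presets 20, 25, 30.
#' @param exclude Genome ids to drop before testing.
#' @return data.table per gene: `gene_id`, `n`, `p_anova`, `p_kruskal`,
#'   BH-adjusted versions, and `direction` (difference of group means,
#'   second factor level minus first, for 2-level factors).
#' @export
gene_averaged_tests <- function(gmatrix, meta, factor_name,
                                min_individuals = 20L,
                                exclude = character(0)) {
  stopifnot(factor_name %in% c("subsistence", "tissue", "sex", "lab"))
  gmatrix <- data.table::as.data.table(gmatrix)
  ids <- setdiff(intersect(names(gmatrix), meta$genome_id), exclude)
  if (length(ids) < 3L) stop_contract("fewer than 3 genomes available")
  grp <- factor(meta[[factor_name]][match(ids, meta$genome_id)])
  m <- as.matrix(gmatrix[, ids, with = FALSE])
  lev <- levels(grp)
  res <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    ok <- !is.na(v)
    if (sum(ok) < min_individuals) return(NULL)
    g <- droplevels(grp[ok]); v <- v[ok]
    if (nlevels(g) < 2L) return(NULL)
    pa <- tryCatch({
      if (stats::var(v) == 0) 1 else
        summary(stats::aov(v ~ g))[[1L]][["Pr(>F)"]][1L]
    }, error = function(e) NA_real_)
    pk <- tryCatch({
      if (stats::var(v) == 0) 1 else
        suppressWarnings(stats::kruskal.test(v, g)$p.value)
    }, error = function(e) NA_real_)
    dir <- if (length(lev) == 2L && all(lev %in% levels(g)))
      mean(v[g == lev[2L]]) - mean(v[g == lev[1L]]) else NA_real_
    data.table::data.table(gene_id = gmatrix$gene_id[i], n = sum(ok),
                           p_anova = pa, p_kruskal = pk, direction = dir)
  })
  res <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (!nrow(res)) return(res)
  res$p_anova_adj <- stats::p.adjust(res$p_anova, method = "BH")
  res$p_kruskal_adj <- stats::p.adjust(res$p_kruskal, method = "BH")
  res[]
}
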