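mk_site <- function(pos, n1, n0, genome = NULL) {
  dt <- data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                               n1 = as.integer(n1), n0 = as.integer(n0))
  dt$ms <- dt$n1 / (dt$n1 + dt$n0)
  dt
}
toy_genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                        strand = "+", start = c(0L, 1000L),
                        end = c(100L, 1100L))

test_that("gene cells average site MS within and across replicates", {
  g1 <- mk_site(c(10, 20), c(0, 1), c(5, 24))   # ms 0 and 0.04
  reps <- list(list(s1 = g1), list(s1 = g1))
  gd <- build_gene_datasets(reps, toy_genes)
  expect_equal(gd$matrix$s1[gd$matrix$gene_id == "gA"], 0.02)
  expect_equal(gd$n_cpg$s1[gd$n_cpg$gene_id == "gA"], 2)

  # a gene present in only some replicates averages over those replicates
  g_rep1 <- mk_site(c(10, 1010), c(1, 1), c(9, 9))    # gA ms .1, gB ms .1
  g_rep2 <- mk_site(10, 3, 7)                          # gB lost in rep 2
  gd2 <- build_gene_datasets(list(list(s1 = g_rep1), list(s1 = g_rep2)),
                             toy_genes)
  expect_equal(gd2$matrix$s1[gd2$matrix$gene_id == "gB"], 0.1)
  expect_equal(gd2$matrix$s1[gd2$matrix$gene_id == "gA"], mean(c(0.1, 0.3)))
})

test_that("the gene matrix equals an independent recomputation", {
  set.seed(5)
  reps <- lapply(1:3, function(r) {
    lapply(stats::setNames(nm = c("x", "y", "z")), function(g) {
      k <- sample(2:5, 1)
      mk_site(sample(c(5, 25, 50, 1005, 1025, 1050), k),
              rpois(k, 1), rpois(k, 4) + 1L)
    })
  })
  gd <- build_gene_datasets(reps, toy_genes)
  # brute force: per gene x genome, mean site ms per replicate, then mean
  for (g in toy_genes$gene_id) {
    lo <- toy_genes$start[toy_genes$gene_id == g]
    hi <- toy_genes$end[toy_genes$gene_id == g]
    for (id in c("x", "y", "z")) {
      per_rep <- vapply(reps, function(rp) {
        s <- rp[[id]]; s <- s[s$pos >= lo & s$pos < hi, ]
        if (nrow(s)) mean(s$ms) else NA_real_
      }, numeric(1))
      want <- if (all(is.na(per_rep))) NA_real_ else mean(per_rep, na.rm = TRUE)
      got <- gd$matrix[[id]][gd$matrix$gene_id == g]
      if (length(got) == 0L) got <- NA_real_
      expect_equal(got, want, label = paste(g, id))
    }
  }
  expect_error(build_gene_datasets(reps, toy_genes[0, ]), "no genes overlap")
})

test_that("stratified ANOVA matches a hand-computed sequential decomposition", {
  meta <- data.frame(genome_id = paste0("g", 1:6),
                     subsistence = c("HG", "HG", "NF", "NF", "NF", "HG"),
                     tissue = c("bone", "tooth", "bone", "tooth", "bone", "bone"),
                     sex = c("XX", "XY", "XY", "XX", "XY", "XX"),
                     lab = c("A", "A", "B", "B", "B", "A"),
                     library = "ds", coverage = 10)
  n1 <- c(3, 5, 2, 8, 1, 4); n0 <- c(37, 55, 18, 52, 29, 46)
  gene_dt <- data.table::data.table(genome_id = meta$genome_id, n1 = n1, n0 = n0)
  got <- fit_stratified_model(gene_dt, meta, "individual")

  # oracle: weighted sequential regression on per-genome means; the fixed
  # factors are constant within genome so the between-genome stratum carries
  # all their information, tested against the between-genome residual MS
  w <- n1 + n0; ybar <- n1 / w
  d <- data.frame(ybar = ybar, subs = factor(meta$subsistence),
                  tis = factor(meta$tissue), sex = factor(meta$sex))
  rss <- function(f) sum(w * stats::resid(stats::lm(f, data = d, weights = w))^2)
  r <- c(rss(ybar ~ 1), rss(ybar ~ subs), rss(ybar ~ subs + tis),
         rss(ybar ~ subs + tis + sex))
  ss <- -diff(r); msr <- r[4] / (6 - 4)
  p_oracle <- stats::pf(ss / msr, 1, 2, lower.tail = FALSE)
  expect_equal(unname(got), unname(p_oracle), tolerance = 1e-10)
})

test_that("degenerate designs are inestimable or null as appropriate", {
  meta <- data.frame(genome_id = paste0("g", 1:6),
                     subsistence = c("HG", "HG", "HG", "NF", "NF", "NF"),
                     tissue = c("bone", "tooth", "bone", "tooth", "bone", "tooth"),
                     sex = c("XX", "XY", "XX", "XY", "XX", "XY"),
                     lab = c("A", "A", "A", "B", "B", "B"),
                     library = "ds", coverage = 10)
  # identical group-level response distributions, balanced -> F = 0, p = 1
  gene_dt <- data.table::data.table(genome_id = meta$genome_id,
                                    n1 = c(4L, 5L, 6L, 4L, 5L, 6L),
                                    n0 = c(46L, 45L, 44L, 46L, 45L, 44L))
  p <- fit_stratified_model(gene_dt, meta, "individual")
  expect_equal(unname(p["subsistence"]), 1, tolerance = 1e-8)
  # all reads deaminated -> constant response, inestimable
  allde <- data.table::data.table(genome_id = meta$genome_id, n1 = 10L, n0 = 0L)
  expect_true(all(is.na(fit_stratified_model(allde, meta, "individual"))))
  # single-level factor -> inestimable
  meta1 <- meta; meta1$subsistence <- "HG"
  expect_true(all(is.na(fit_stratified_model(gene_dt, meta1, "individual"))))
})

test_that("swapping factor level labels leaves the p-values unchanged", {
  meta <- data.frame(genome_id = paste0("g", 1:6),
                     subsistence = c("HG", "NF", "HG", "NF", "HG", "NF"),
                     tissue = c("bone", "bone", "tooth", "tooth", "bone", "tooth"),
                     sex = c("XX", "XY", "XY", "XX", "XY", "XX"),
                     lab = rep(c("A", "B"), 3), library = "ds", coverage = 10)
  set.seed(8)
  gene_dt <- data.table::data.table(genome_id = meta$genome_id,
                                    n1 = rpois(6, 4) + 1L, n0 = rpois(6, 40))
  p1 <- fit_stratified_model(gene_dt, meta, "individual")
  meta2 <- meta
  meta2$subsistence <- ifelse(meta$subsistence == "HG", "NF", "HG")
  p2 <- fit_stratified_model(gene_dt, meta2, "individual")
  expect_equal(p1, p2)
})

test_that("the battery BH-corrects per model, factor and replicate", {
  set.seed(12)
  meta <- data.frame(genome_id = paste0("g", 1:8),
                     subsistence = rep(c("HG", "NF"), 4),
                     tissue = rep(c("bone", "tooth"), each = 4),
                     sex = rep(c("XX", "XY"), c(4, 4))[sample.int(8)],
                     lab = rep(c("A", "B"), each = 4),
                     library = "ds", coverage = 10)
  full <- data.table::rbindlist(lapply(1:2, function(r)
    data.table::rbindlist(lapply(paste0("G", 1:5), function(g) {
      dt <- data.table::data.table(genome_id = meta$genome_id, chrom = "chr1",
                                   pos = 1L, n1 = rpois(8, 3) + 1L,
                                   n0 = rpois(8, 60))
      dt$ms <- dt$n1 / (dt$n1 + dt$n0); dt$gene_id <- g; dt$replicate <- r
      dt
    }))))
  bat <- run_model_battery(full, meta)
  res <- bat$results
  for (key in split(seq_len(nrow(res)),
                    paste(res$model, res$factor, res$replicate))) {
    expect_equal(res$p_adj[key], stats::p.adjust(res$p[key], "BH"))
  }
  # textbook BH step-up arithmetic through the same adjustment route
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("gene-averaged tests match a hand-ranked Kruskal-Wallis with ties", {
  vals <- c(1, 2, 2, 3, 4, 4)
  grp <- c("a", "a", "b", "b", "a", "b")
  meta <- data.frame(genome_id = paste0("g", 1:6),
                     subsistence = ifelse(grp == "a", "HG", "NF"),
                     tissue = "bone", sex = "XX", lab = "A",
                     library = "ds", coverage = 10)
  gm <- data.table::data.table(gene_id = "G1")
  for (i in 1:6) gm[[paste0("g", i)]] <- vals[i]
  res <- gene_averaged_tests(gm, meta, "subsistence", min_individuals = 6L)
  r <- rank(vals); N <- 6
  Rbar <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rbar^2 / table(grp)) - 3 * (N + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  p_hand <- stats::pchisq(H, df = 1, lower.tail = FALSE)
  expect_equal(res$p_kruskal, p_hand, tolerance = 1e-12)
  # identical values in both groups -> p = 1
  gm2 <- gm; for (i in 1:6) gm2[[paste0("g", i)]] <- 0.5
  res2 <- gene_averaged_tests(gm2, meta, "subsistence", min_individuals = 6L)
  expect_equal(res2$p_kruskal, 1)
  expect_equal(res2$p_anova, 1)
  # min_individuals filter drops under-observed genes
  expect_equal(nrow(gene_averaged_tests(gm, meta, "subsistence",
                                        min_individuals = 7L)), 0L)
})
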