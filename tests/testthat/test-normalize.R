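# spread pooled totals (N1, N0) over k sites for subsampling tests
spread_counts <- function(N1, N0, k = 40L, seed = 1L) {
  withr::with_seed(seed, {
    n1 <- as.integer(stats::rmultinom(1L, N1, rep(1, k)))
    n0 <- as.integer(stats::rmultinom(1L, N0, rep(1, k)))
    data.table::data.table(chrom = "chr1", pos = seq_len(k) * 10L,
                           n1 = n1, n0 = n0)
  })
}

test_that("below-target genomes keep all deaminated reads at the 49x rule", {
  cnt <- spread_counts(100L, 9900L)          # pooled mean 0.01
  nm <- normalize_genome(cnt, 0.02, seed = 5L)
  expect_equal(attr(nm, "case"), "a")
  expect_equal(attr(nm, "N1s"), 100L)        # all deaminated retained
  expect_equal(attr(nm, "N0s"), 4900L)       # 49 x N1 non-deaminated drawn
  expect_equal(attr(nm, "achieved"), 0.02)
  expect_true(all(nm$n1 + nm$n0 > 0L))
})

test_that("above-target genomes subsample deaminated reads to N0/49", {
  cnt <- spread_counts(500L, 9500L)          # pooled mean 0.05
  nm <- normalize_genome(cnt, 0.02, seed = 6L)
  expect_equal(attr(nm, "case"), "b")
  expect_equal(attr(nm, "N1s"), 194L)        # round(9500/49)
  expect_equal(attr(nm, "N0s"), 9500L)
  expect_equal(attr(nm, "achieved"), 194 / 9694)
  ach <- attr(nm, "achieved")
  expect_lte(abs(ach - 0.02), 1 / (194 + 9500))
})

test_that("genomes already at the target are returned unchanged", {
  cnt <- spread_counts(200L, 9800L)          # exactly 0.02
  nm <- normalize_genome(cnt, 0.02, seed = 7L)
  expect_equal(attr(nm, "case"), "identity")
  expect_equal(nm$n1, cnt$n1[cnt$n1 + cnt$n0 > 0])
  expect_equal(nm$n0, cnt$n0[cnt$n1 + cnt$n0 > 0])
})

test_that("subsampling never exceeds per-site counts and reduces one side only", {
  cnt <- spread_counts(300L, 5000L, k = 25L, seed = 3L)  # mean > 0.02
  for (s in 1:20) {
    nm <- normalize_genome(cnt, 0.02, seed = s)
    m <- merge(cnt, nm, by = c("chrom", "pos"), all.x = TRUE)
    m[is.na(m)] <- 0L
    expect_true(all(m$n1.y <= m$n1.x))
    expect_true(all(m$n0.y == m$n0.x | m$n1.y + m$n0.y == 0L))
    ach <- attr(nm, "achieved")
    expect_lte(abs(ach - 0.02), 1 / (attr(nm, "N1s") + attr(nm, "N0s")))
  }
})

test_that("a genome with no deaminated reads cannot reach the target", {
  cnt <- data.table::data.table(chrom = "c", pos = 1:3, n1 = 0L, n0 = 100L)
  expect_error(normalize_genome(cnt, 0.02, genome_id = "A07"), "A07")
})

test_that("per-site allocation is hypergeometric in expectation", {
  cnt <- data.table::data.table(chrom = "c", pos = 1:3,
                                n1 = c(2L, 5L, 13L), n0 = c(300L, 900L, 1800L))
  # pooled 20/3020 ~ 0.0066 < 0.02 -> case (a): draw K0 = 49*20 = 980 of 3000
  draws <- sapply(1:2000, function(s)
    merge(cnt[, c("chrom", "pos")],
          normalize_genome(cnt, 0.02, seed = s), by = c("chrom", "pos"),
          all.x = TRUE)$n0)
  K0 <- 980; N0 <- 3000
  expected <- cnt$n0 * K0 / N0
  sds <- sqrt(K0 * (cnt$n0 / N0) * (1 - cnt$n0 / N0) * (N0 - K0) / (N0 - 1))
  obs <- rowMeans(draws)
  expect_true(all(abs(obs - expected) <= 3 * sds / sqrt(2000) + 1e-9))
})

test_that("replicate datasets are reproducible, distinct, and share totals", {
  cl <- list(g1 = spread_counts(80L, 9000L, seed = 11L),
             g2 = spread_counts(700L, 9000L, seed = 12L))
  r1 <- make_replicates(cl, 0.02, R = 3L, base_seed = 99L)
  r2 <- make_replicates(cl, 0.02, R = 3L, base_seed = 99L)
  expect_equal(r1$replicates, r2$replicates)
  expect_equal(r1$manifest, r2$manifest)
  # all replicates hit the target within one read
  expect_true(all(abs(r1$manifest$achieved - 0.02) <=
                    1 / (r1$manifest$N1s + r1$manifest$N0s)))
  # same per-genome totals across replicates, but different site allocations
  tot <- tapply(r1$manifest$N1s + r1$manifest$N0s, r1$manifest$genome_id,
                function(x) length(unique(x)))
  expect_true(all(tot == 1L))
  expect_false(identical(r1$replicates[[1L]]$g2$n1, r1$replicates[[2L]]$g2$n1))
})

test_that("chrX profiles divide by the genome's autosomal mean", {
  x <- data.table::data.table(genome_id = c("a", "a", "b"),
                              ms = c(0.04, 0.02, 0.03))
  out <- normalize_chrx(x, c(a = 0.02, b = 0.03))
  expect_equal(out$ratio, c(2, 1, 1))
  expect_error(normalize_chrx(x, c(a = 0.02, b = 0)), "positive")
  expect_error(normalize_chrx(x, c(a = 0.02)), "missing autosomal mean")
})

test_that("chrX replicates reuse the autosomal case and retention fraction", {
  auto <- list(g1 = spread_counts(100L, 9900L, seed = 21L),   # case a, f0 = 4900/9900
               g2 = spread_counts(700L, 9000L, seed = 22L))   # case b, f1 = 184/700
  chrx <- list(g1 = spread_counts(30L, 2000L, k = 10L, seed = 23L),
               g2 = spread_counts(150L, 2000L, k = 10L, seed = 24L))
  out <- make_chrx_replicates(chrx, auto, target_ms = 0.02, R = 2L,
                              base_seed = 7L)
  m <- out$manifest
  expect_equal(unique(m$case[m$genome_id == "g1"]), "a")
  expect_equal(unique(m$case[m$genome_id == "g2"]), "b")
  expect_equal(unique(m$fraction[m$genome_id == "g1"]), 4900 / 9900)
  expect_equal(unique(m$fraction[m$genome_id == "g2"]),
               round(9000 / 49) / 700)
  r1 <- out$replicates[[1L]]
  # case a: chrX deaminated reads untouched, non-deaminated thinned by f0
  expect_equal(sum(r1$g1$n1), 30L)
  expect_equal(sum(r1$g1$n0), round(2000 * 4900 / 9900))
  # case b: chrX non-deaminated untouched, deaminated thinned by f1
  expect_equal(sum(r1$g2$n0), 2000L)
  expect_equal(sum(r1$g2$n1), round(150 * round(9000 / 49) / 700))
  # per-site counts never exceed originals
  mm <- merge(chrx$g2, r1$g2, by = c("chrom", "pos"))
  expect_true(all(mm$n1.y <= mm$n1.x))
  # achieved autosomal mean recorded for the ratio scale
  expect_equal(unique(m$achieved_auto[m$genome_id == "g1"]), 100 / 5000)
})
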