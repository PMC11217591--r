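cat10 <- data.table::data.table(chrom = "chr1", pos = 10L,
                                chrom_class = "autosome")

test_that("read filters apply the 35 bp / MAPQ 30 / 10 percent rules", {
  seq36 <- strrep("A", 36)
  reads <- data.table::data.table(
    qname = paste0("r", 1:6), chrom = "chr1",
    start = 0L,
    end = c(34L, 35L, 36L, 40L, 40L, 40L),
    strand = "+",
    mapq = c(60L, 30L, 29L, 60L, 60L, 60L),
    nm = c(0L, 0L, 0L, 5L, 4L, 0L),
    seq = substr(seq36, 1, c(34, 35, 36, 40, 40, 40)))
  kept <- filter_reads(reads)
  # r1: 34 bp (dropped); r2: 35 bp MAPQ 30 (kept); r3: MAPQ 29 (dropped);
  # r4: 5/40 = 12.5% mismatches (dropped); r5: 4/40 = 10% (kept); r6 kept
  expect_setequal(kept$qname, c("r2", "r5", "r6"))
  reads$nm <- NA_integer_
  expect_error(filter_reads(reads), "NM")
})

test_that("site evidence counts read out T/C (A/G) at eligible ends only", {
  # forward read starting exactly at the CpG C, damaged base T
  r <- make_reads("chr1", 10L, paste0("T", strrep("A", 39)))
  cnt <- count_site_evidence(r, cat10, "ds", damage_window = 20L)
  expect_equal(cnt$n1, 1L); expect_equal(cnt$n0, 0L); expect_equal(cnt$ms, 1)

  # ten forward reads, 3 with T and 7 with C at the site -> MS 0.3
  r10 <- make_reads("chr1", rep(10L, 10),
                    paste0(c(rep("T", 3), rep("C", 7)), strrep("A", 39)))
  cnt <- count_site_evidence(r10, cat10, "ds")
  expect_equal(cnt$n1, 3L); expect_equal(cnt$n0, 7L); expect_equal(cnt$ms, 0.3)

  # reverse read: evidence is the G at pos+1, read out as A when deaminated;
  # 5' end of a reverse read is its right edge
  cat30 <- data.table::data.table(chrom = "chr1", pos = 30L)
  rv <- make_reads("chr1", 0L, paste0(strrep("T", 31), "A", strrep("T", 3)),
                   strand = "-")  # A at ref pos 31 = G of the CpG at 30
  cnt <- count_site_evidence(rv, cat30, "ds")
  expect_equal(cnt$n1, 1L); expect_equal(cnt$n0, 0L)

  # a base that is neither C/T (G/A) contributes nothing
  rg <- make_reads("chr1", 10L, paste0("G", strrep("A", 39)))
  expect_equal(nrow(count_site_evidence(rg, cat10, "ds")), 0L)
})

test_that("library chemistry decides which read ends are eligible", {
  # site at offset 30 of a 40 bp forward read: only the 3' window covers it
  r <- make_reads("chr1", 0L, paste0(strrep("A", 30), "C", strrep("A", 9)))
  cat30 <- data.table::data.table(chrom = "chr1", pos = 30L)
  expect_equal(nrow(count_site_evidence(r, cat30, "ds", 20L)), 0L)
  ss <- count_site_evidence(r, cat30, "ss", 20L)
  expect_equal(ss$n0, 1L)

  # both windows of a short ss read cover the site: one contribution only
  r35 <- make_reads("chr1", 0L, paste0(strrep("A", 17), "T", strrep("A", 17)))
  cat17 <- data.table::data.table(chrom = "chr1", pos = 17L)
  both <- count_site_evidence(r35, cat17, "ss", 20L)
  expect_equal(both$n1 + both$n0, 1L)
})

test_that("reads on a chromosome missing from the catalog are rejected", {
  r <- make_reads("chrZ", 10L, strrep("A", 40))
  expect_error(count_site_evidence(r, cat10, "ds"), "absent from the catalog")
})

test_that("depth filtering keeps >= min_depth sites, monotonically", {
  set.seed(7)
  toy <- data.table::data.table(chrom = "chr1", pos = 1:50,
                                n1 = rpois(50, 1), n0 = rpois(50, 3))
  f4 <- apply_depth_filter(toy, 4L)
  expect_equal(nrow(f4), sum(toy$n1 + toy$n0 >= 4))     # brute-force recount
  expect_true(all(f4$n1 + f4$n0 >= 4))
  expect_equal(nrow(apply_depth_filter(toy, 1L)), sum(toy$n1 + toy$n0 >= 1))
  survivors <- vapply(1:6, function(k) nrow(apply_depth_filter(toy, k)), integer(1))
  expect_true(all(diff(survivors) <= 0))
  expect_equal(nrow(apply_depth_filter(toy, "strict")),
               sum(toy$n1 + toy$n0 >= 10))
})

test_that("pooling is read-weighted and rejects empty sets", {
  two <- data.table::data.table(chrom = "c", pos = 1:2, n1 = c(1L, 3L),
                                n0 = c(9L, 7L))
  expect_equal(pool_mean_ms(two)$ms, 0.2)
  expect_equal(pool_mean_ms(data.table::data.table(chrom = "c", pos = 1:3,
                                                   n1 = 0L, n0 = 5L))$ms, 0)
  expect_error(pool_mean_ms(two[0L, ]), "empty")
})

test_that("matrix assembly outer-joins genomes with explicit missingness", {
  g1 <- data.table::data.table(chrom = "c", pos = c(1L, 2L), n1 = 1L, n0 = 1L,
                               ms = c(0.5, 0.5))
  g2 <- data.table::data.table(chrom = "c", pos = c(3L, 4L), n1 = 1L, n0 = 3L,
                               ms = c(0.25, 0.25))
  g3 <- data.table::data.table(chrom = "c", pos = c(2L, 3L), n1 = 0L, n0 = 4L,
                               ms = c(0, 0))
  m <- assemble_matrix(list(a = g1, b = g2, c = g3))
  expect_equal(nrow(m), 4L)
  expect_equal(sum(stats::complete.cases(m)), 0L)  # no site in all genomes
  # hand enumeration of per-row missingness
  expect_equal(rowSums(is.na(m[, c("a", "b", "c")])), c(2, 1, 1, 2))
  expect_equal(nrow(assemble_matrix(list(solo = g1))), nrow(g1))
  expect_error(assemble_matrix(stats::setNames(list(g1, g2), c("a", "a"))),
               "uniquely named")
})

test_that("context summaries average per class and test island contrast", {
  mk <- function(i_ms, o_ms) data.table::data.table(
    chrom = "c", pos = 1:4, n1 = 1L, n0 = 1L, ms = c(i_ms, i_ms, o_ms, o_ms),
    context = c("island", "island", "open_sea", "open_sea"))
  cl <- list(g1 = mk(0, 0.04), g2 = mk(0.01, 0.05), g3 = mk(0, 0.03))
  cs <- context_summary(cl)
  expect_equal(cs$summary$island, c(0, 0.01, 0))
  expect_equal(cs$summary$open_sea, c(0.04, 0.05, 0.03))
  expect_lt(cs$tests$p[cs$tests$context == "open_sea"], 0.2)
  # identical class means across genomes -> one-sided p = 1
  same <- list(g1 = mk(0.02, 0.02), g2 = mk(0.02, 0.02), g3 = mk(0.02, 0.02))
  expect_equal(context_summary(same)$tests$p, 1)
})
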