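#' Co-directionality of methylation differences between two datasets
#'
#' Spearman rank correlation (tie-corrected, normal approximation) between
#' per-gene farmer-minus-hunter-gatherer methylation differences and an
#' external table of per-gene log fold-changes, over the genes the two share.
#' Invariant to monotone transforms of either input.
#'
#' @param delta_a data.frame with `gene_id` and `delta`
#'   (see [delta_ms_by_gene()]).
#' @param table_b data.frame with `gene` (or `gene_id`) and `logFC`.
#' @param min_overlap Minimum number of shared genes.
#' @return list with `n`, `r` (Spearman), `p`.
#' @export
codirectionality <- function(delta_a, table_b, min_overlap = 3L) {
  key_b <- if ("gene" %in% names(table_b)) "gene" else "gene_id"
  common <- intersect(delta_a$gene_id, table_b[[key_b]])
  if (length(common) < min_overlap)
    stop_contract("only ", length(common), " overlapping genes (need >= ",
                  min_overlap, ")")
  x <- delta_a$delta[match(common, delta_a$gene_id)]
  y <- table_b$logFC[match(common, table_b[[key_b]])]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(n = length(common), r = unname(ct$estimate), p = ct$p.value)
}

#' All-pairs co-directionality matrix
#'
#' Compares every pair among a set of per-gene difference tables (ancient
#' sub-datasets and/or external modern tables), reporting Spearman r in the
#' upper triangle and the p-value in the lower triangle, as conventionally
#' tabulated.
#'
#' @param tables Named list; each element a data.frame with `gene_id` (or
#'   `gene`) and a value column (`delta` or `logFC`).
#' @param min_overlap Minimum shared genes per pair.
#' @return list with `r`, `p` and `n` matrices and a combined display
#'   data.frame (`r` upper triangle, `p` lower).
#' @export
codirectionality_matrix <- function(tables, min_overlap = 3L) {
  nm <- names(tables)
  stopifnot(!is.null(nm), all(nzchar(nm)))
  std <- lapply(tables, function(t) {
    key <- if ("gene" %in% names(t)) "gene" else "gene_id"
    val <- if ("delta" %in% names(t)) "delta" else "logFC"
    data.frame(gene_id = t[[key]], delta = t[[val]])
  })
  k <- length(std)
  rmat <- pmat <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    cd <- codirectionality(std[[i]],
                           data.frame(gene = std[[j]]$gene_id,
                                      logFC = std[[j]]$delta),
                           min_overlap)
    rmat[i, j] <- rmat[j, i] <- cd$r
    pmat[i, j] <- pmat[j, i] <- cd$p
    nmat[i, j] <- nmat[j, i] <- cd$n
  }
  disp <- matrix("-", k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) disp[i, j] <- sprintf("r = %.3f", rmat[i, j])
    if (j < i) disp[i, j] <- sprintf("p = %.3g", pmat[i, j])
  }
  list(r = rmat, p = pmat, n = nmat, display = as.data.frame(disp))
}
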