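#' Multidimensional scaling of genome-wide methylation profiles
#'
#' Classical (Torgerson) MDS of the pairwise Euclidean distances between
#' genomes' gene-averaged MS profiles. By default distances are computed
#' over complete-case genes (no missing cell in any retained genome); a
#' pairwise-complete alternative rescales each pair's squared distance by
#' the fraction of genes the pair shares.
#'
#' @param gmatrix Gene-averaged matrix (`gene_id` + genome columns).
#' @param exclude Genome ids to drop before embedding (e.g. known outliers).
#' @param k Number of dimensions.
#' @param pairwise Use pairwise-complete genes with distance rescaling
#'   instead of complete cases.
#' @return list with `coords` (data.frame `genome_id`, `dim1..dimk`),
#'   `eig_share` (proportion of positive eigenvalue mass per dimension) and
#'   `n_genes` (genes used; for pairwise mode the total non-empty genes).
#' @export
mds_profiles <- function(gmatrix, exclude = character(0), k = 2L,
                         pairwise = FALSE) {
  gmatrix <- data.table::as.data.table(gmatrix)
  ids <- setdiff(setdiff(names(gmatrix), "gene_id"), exclude)
  if (length(ids) < 3L) stop_contract("need at least 3 genomes after exclusion")
  m <- t(as.matrix(gmatrix[, ids, with = FALSE]))  # genomes x genes
  if (pairwise) {
    G <- ncol(m)
    d2 <- matrix(0, nrow(m), nrow(m))
    for (i in seq_len(nrow(m) - 1L)) for (j in seq(i + 1L, nrow(m))) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) stop_contract("genomes ", ids[i], " and ", ids[j],
                                  " share no genes")
      d2[i, j] <- d2[j, i] <- sum((m[i, ok] - m[j, ok])^2) * G / sum(ok)
    }
    d <- stats::as.dist(sqrt(d2))
    n_genes <- G
  } else {
    keep <- colSums(is.na(m)) == 0L
    if (!any(keep)) stop_contract("no complete-case genes for MDS")
    d <- stats::dist(m[, keep, drop = FALSE])
    n_genes <- sum(keep)
  }
  fit <- stats::cmdscale(d, k = min(k, nrow(m) - 1L), eig = TRUE)
  coords <- data.frame(genome_id = ids, fit$points)
  names(coords) <- c("genome_id", paste0("dim", seq_len(ncol(fit$points))))
  pos <- fit$eig[fit$eig > 0]
  list(coords = coords,
       eig_share = fit$eig[seq_len(ncol(fit$points))] / sum(pos),
       n_genes = n_genes)
}
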