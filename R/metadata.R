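#' Laboratory profiles for the synthetic cohort
#'
#' Each producing laboratory is characterized by a terminal deamination
#' probability `d` (the dominant driver of a genome's mean methylation score:
#' pooled MS is approximately `mean(m) * d`), a mean depth-of-coverage, a
#' fragment-length distribution and a library chemistry. Defaults spread `d`
#' over 0.015-0.09 so that, with a genome-wide true methylation around 0.65,
#' per-genome mean MS spans roughly 1-6 percent - the multiple-fold spread
#' observed among published UDG-treated paleogenomes. Laboratories also
#' differ in coverage, the second ingredient of laboratory batch structure.
#'
#' Beyond the scalar `d`, each laboratory carries a regional
#' damage-recovery pattern: the effective damage rate varies over 10 kb
#' regions by a lab-specific lognormal factor (`exp(N(0, regional_sd))`,
#' deterministic given the lab id). This emulates protocol-driven regional
#' technical variation - the kind of lab-coherent heterogeneity that genome-
#' wide mean normalization cannot remove and that makes methylation profiles
#' cluster by producing laboratory. Set `regional_sd = 0` for perfectly
#' uniform labs.
#'
#' @param n_labs Number of laboratories.
#' @param d Deamination probabilities, recycled to `n_labs`; all in (0, 1).
#' @param coverage Mean depth-of-coverage per lab, recycled.
#' @param library Library chemistry per lab, `"ds"` (double-stranded, damage
#'   read out at the 5' end only) or `"ss"` (single-stranded, both ends).
#' @param frag_mean,frag_sd Mean and sd of the (lognormal, discretized,
#'   floored at 35 bp) fragment-length distribution.
#' @param regional_sd SD of the lab-specific log damage-recovery factor over
#'   10 kb regions.
#' @return data.frame with one row per laboratory.
#' @export
lab_profiles <- function(n_labs = 6L,
                         d = seq(0.015, 0.09, length.out = n_labs),
                         coverage = seq(8, 28, length.out = n_labs),
                         library = c(rep("ds", n_labs - 1L), "ss"),
                         frag_mean = 60, frag_sd = 15, regional_sd = 0.25) {
  d <- rep_len(d, n_labs); coverage <- rep_len(coverage, n_labs)
  library <- rep_len(library, n_labs)
  stopifnot(all(d > 0 & d < 1), all(coverage > 0),
            all(library %in% c("ds", "ss")), all(regional_sd >= 0))
  sdlog <- sqrt(log(1 + (frag_sd / frag_mean)^2))
  data.frame(lab = paste0("L", seq_len(n_labs)), d = d, coverage = coverage,
             library = library,
             frag_meanlog = log(frag_mean) - sdlog^2 / 2, frag_sdlog = sdlog,
             regional_sd = rep_len(regional_sd, n_labs),
             stringsAsFactors = FALSE)
}

# Deterministic per-lab, per-site damage-rate multipliers over 10 kb regions.
lab_region_multiplier <- function(lab_row, sites, region_bp = 10000L) {
  rsd <- lab_row$regional_sd %||% 0
  if (is.null(rsd) || is.na(rsd) || rsd == 0) return(rep(1, nrow(sites)))
  lab_seed <- (sum(utf8ToInt(lab_row$lab)) * 2654435L) %% 2147483587L
  key <- paste0(sites$chrom, ":", sites$pos %/% region_bp)
  regions <- sort(unique(key))
  z <- with_seed(lab_seed, stats::rnorm(length(regions), 0, rsd))
  exp(z)[match(key, regions)]
}

#' Sample metadata sheet for a synthetic cohort
#'
#' Builds the genome-level label table the downstream statistics consume:
#' subsistence (hunter-gatherer `HG` vs Neolithic farmer `NF`), tissue
#' (bone/tooth), genetic sex (XX/XY), laboratory-of-origin, library type and
#' target coverage. The default sizes mirror the cohort structure the
#' pipeline is designed for: 34 genomes, 13 HG / 21 NF, 12 female / 22 male,
#' 23 bone / 11 tooth, six laboratories of which one (the `ss` lab) produced
#' four single-stranded libraries. Factors are assigned to genomes
#' independently at random under the seed; per-genome coverage is drawn
#' uniformly from `coverage_range` around the lab means in `labs`.
#'
#' @param n Number of genomes.
#' @param n_hg,n_female,n_tooth Counts of HG, XX and tooth genomes.
#' @param labs A [lab_profiles()] data.frame.
#' @param coverage_range Range of per-genome coverages; per-genome coverage is
#'   the lab mean jittered by +-30 percent, clamped to this range.
#' @param seed Integer seed.
#' @return data.frame with columns `genome_id`, `subsistence`, `tissue`,
#'   `sex`, `lab`, `library`, `coverage`.
#' @export
cohort_metadata <- function(n = 34L, n_hg = 13L, n_female = 12L, n_tooth = 11L,
                            labs = lab_profiles(),
                            coverage_range = c(5, 30), seed = 1L) {
  stopifnot(n_hg <= n, n_female <= n, n_tooth <= n, nrow(labs) >= 1)
  with_seed(seed, {
    lab_sizes <- rep(n %/% nrow(labs), nrow(labs))
    lab_sizes[seq_len(n %% nrow(labs))] <- lab_sizes[seq_len(n %% nrow(labs))] + 1L
    lab_assign <- sample(rep(labs$lab, lab_sizes))
    meta <- data.frame(
      genome_id = sprintf("A%02d", seq_len(n)),
      subsistence = sample(rep(c("HG", "NF"), c(n_hg, n - n_hg))),
      tissue = sample(rep(c("tooth", "bone"), c(n_tooth, n - n_tooth))),
      sex = sample(rep(c("XX", "XY"), c(n_female, n - n_female))),
      lab = lab_assign, stringsAsFactors = FALSE)
    li <- match(meta$lab, labs$lab)
    meta$library <- labs$library[li]
    cov <- labs$coverage[li] * stats::runif(n, 0.7, 1.3)
    meta$coverage <- pmin(max(coverage_range), pmax(min(coverage_range), cov))
    meta
  })
}

check_meta <- function(meta) {
  assert_columns(meta, c("genome_id", "subsistence", "tissue", "sex", "lab",
                         "library", "coverage"), "metadata")
  stopifnot(all(meta$subsistence %in% c("HG", "NF")),
            all(meta$tissue %in% c("bone", "tooth")),
            all(meta$sex %in% c("XX", "XY")),
            all(meta$library %in% c("ss", "ds")),
            all(meta$coverage > 0),
            !anyDuplicated(meta$genome_id))
  invisible(meta)
}

#' Write / read a cohort metadata sheet
#'
#' @param meta Metadata data.frame as from [cohort_metadata()].
#' @param path TSV file path.
#' @return `path` (write) or the metadata data.frame (read).
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(check_meta(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  check_meta(utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}
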