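#' Simulate UDG-treated aligned reads for one genome
#'
#' Emits aDNA-like fragments aligned to the synthetic reference, carrying
#' postmortem deamination of methylated cytosines at CpG sites near fragment
#' termini. UDG treatment is modeled as removing all unmethylated-cytosine
#' deamination, so the only damage emitted is C->T at CpG cytosines (G->A in
#' reference orientation for reverse-strand fragments), each with probability
#' `m * d` when the site lies within `damage_window` bases of an eligible
#' fragment end: the 5' end for double-stranded libraries, both ends for
#' single-stranded ones. A site covered by both eligible ends of the same
#' fragment contributes once (the 5' end wins). Fragments are placed
#' uniformly; counts are Poisson-targeted at the genome's coverage, halved on
#' chrX for XY genomes (one X copy). Apart from damage, reads match the
#' reference exactly (no sequencing error, indels or contamination).
#'
#' A truth ledger records every eligible CpG contribution (damaged or not),
#' so scoring output can be checked against the simulation exactly.
#'
#' @param bundle A `ref_bundle`.
#' @param truth A `truth_methylome` over the same bundle.
#' @param meta_row One row of a [cohort_metadata()] sheet (the genome).
#' @param labs A [lab_profiles()] data.frame containing `meta_row$lab`.
#' @param damage_window Width in bp of the terminal window within which a
#'   CpG cytosine can appear deaminated. Default 20, calibrated so that at
#'   typical paleogenome coverages the fraction of CpG sites reaching the
#'   4-read evidence threshold matches what UDG-treated datasets show.
#' @param seed Integer seed.
#' @return list with `reads` (data.table: `qname`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, `mapq`, `nm`, `seq`) and `ledger`
#'   (data.table: `qname`, `chrom`, `pos` (the CpG C position), `orient`,
#'   `damaged`).
#' @export
simulate_genome_reads <- function(bundle, truth, meta_row, labs,
                                  damage_window = 20L, seed = 1L) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(truth, "truth_methylome"))
  if (is.null(meta_row$genome_id) || !nrow(meta_row))
    stop_contract("genome absent from metadata")
  lab <- labs[labs$lab == meta_row$lab, , drop = FALSE]
  if (!nrow(lab)) stop_contract("lab ", meta_row$lab, " not found in lab profiles")
  W <- as.integer(damage_window)
  sites <- truth$sites

  # effective per-site methylation for this genome
  m_eff <- if (identical(meta_row$subsistence, "NF")) sites$m_nf else sites$m
  fac <- truth$params$chrx_female_factor %||% 1
  if (identical(meta_row$sex, "XX") && fac != 1) {
    on_x <- sites$chrom == "chrX"
    m_eff[on_x] <- clamp01(m_eff[on_x] * fac)
  }

  # site-level effective damage rate: scalar lab d times the lab's regional
  # recovery pattern (deterministic per lab), clamped to probability range
  d_site <- pmin(1, lab$d * lab_region_multiplier(lab, sites))
  ss <- identical(meta_row$library, "ss")

  with_seed(seed, {
    reads_l <- list(); ledg_l <- list()
    for (ch in names(bundle$seq)) {
      L <- bundle$chrom_lengths[[ch]]
      cov <- meta_row$coverage
      if (ch == "chrX" && identical(meta_row$sex, "XY")) cov <- cov / 2
      n <- stats::rpois(1L, cov * L / exp(lab$frag_meanlog + lab$frag_sdlog^2 / 2))
      if (n == 0L) next
      len <- pmax(35L, as.integer(round_half_up(
        stats::rlnorm(n, lab$frag_meanlog, lab$frag_sdlog))))
      len <- pmin(len, L)
      start <- as.integer(floor(stats::runif(n, 0, L - len + 1)))  # 0-based
      end <- start + len
      strand <- sample(c("+", "-"), n, replace = TRUE)

      # site lookup vectors: 1-based index over the chromosome
      idx <- which(sites$chrom == ch)
      posC <- integer(L); posG <- integer(L)
      posC[sites$pos[idx] + 1L] <- idx
      posG[sites$pos[idx] + 2L] <- idx

      fwd <- which(strand == "+"); rev <- which(strand == "-")
      win <- function(readix, five_prime, prio) {
        if (!length(readix)) return(NULL)
        rix <- rep(readix, each = W)
        off <- rep.int(seq_len(W) - 1L, length(readix))
        p <- if (five_prime) start[rix] + off else end[rix] - 1L - off
        # orientation of the read decides which strand's cytosine is read out
        is_fwd <- strand[rix[1L]] == "+"
        site <- if (is_fwd) posC[p + 1L] else posG[p + 1L]
        keep <- site > 0L & p >= start[rix] & p < end[rix]
        if (!any(keep)) return(NULL)
        data.table::data.table(read = rix[keep], site = site[keep],
                               refpos = p[keep], prio = prio)
      }
      pr <- list(win(fwd, TRUE, 1L), win(rev, FALSE, 1L))
      if (ss) pr <- c(pr, list(win(fwd, FALSE, 2L), win(rev, TRUE, 2L)))
      pairs <- data.table::rbindlist(pr[!vapply(pr, is.null, logical(1))])
      dam_count <- integer(n)
      seqs <- as.character(Biostrings::extractAt(
        bundle$seq[[ch]], IRanges::IRanges(start + 1L, end)))
      if (nrow(pairs)) {
        data.table::setorderv(pairs, c("read", "site", "prio"))
        pairs <- pairs[!duplicated(pairs[, c("read", "site")]), ]
        pairs$damaged <- stats::runif(nrow(pairs)) <
          m_eff[pairs$site] * d_site[pairs$site]
        dmg <- pairs[pairs$damaged, ]
        if (nrow(dmg)) {
          sub <- ifelse(strand[dmg$read] == "+", "T", "A")
          o <- dmg$refpos - start[dmg$read] + 1L
          for (k in seq_len(nrow(dmg))) {
            r <- dmg$read[k]
            substr(seqs[r], o[k], o[k]) <- sub[k]
          }
          tb <- table(dmg$read)
          dam_count[as.integer(names(tb))] <- as.integer(tb)
        }
        ledg_l[[ch]] <- data.table::data.table(
          qname = paste0(meta_row$genome_id, "_", ch, "_", pairs$read),
          chrom = ch, pos = sites$pos[pairs$site],
          orient = strand[pairs$read], damaged = pairs$damaged)
      }
      reads_l[[ch]] <- data.table::data.table(
        qname = paste0(meta_row$genome_id, "_", ch, "_", seq_len(n)),
        chrom = ch, start = start, end = end, strand = strand,
        mapq = 60L, nm = dam_count, seq = seqs)
    }
    list(reads = data.table::rbindlist(reads_l),
         ledger = if (length(ledg_l)) data.table::rbindlist(ledg_l) else
           data.table::data.table(qname = character(0), chrom = character(0),
                                  pos = integer(0), orient = character(0),
                                  damaged = logical(0)))
  })
}

#' Recount the truth ledger into per-site evidence counts
#'
#' Independent recount of a simulation truth ledger: per CpG site, the number
#' of damaged (`n1`) and undamaged (`n0`) eligible read contributions. Used
#' as the oracle against which [count_site_evidence()] is compared.
#'
#' @param ledger Ledger data.table from [simulate_genome_reads()].
#' @return data.table with `chrom`, `pos`, `n1`, `n0`.
#' @export
ledger_site_counts <- function(ledger) {
  dt <- data.table::as.data.table(ledger)
  out <- dt[, list(n1 = sum(damaged), n0 = sum(!damaged)),
            by = c("chrom", "pos")]
  data.table::setorderv(out, c("chrom", "pos"))
  out[]
}

#' Write simulated reads as a coordinate-sorted, indexed BAM
#'
#' @param reads Read table from [simulate_genome_reads()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param prefix Output path without extension; `<prefix>.bam` (+ `.bai`) is
#'   created.
#' @return Path to the BAM file.
#' @export
write_genome_bam <- function(reads, chrom_lengths, prefix) {
  reads <- data.table::as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  reads$qname, flag, reads$chrom, reads$start + 1L,
                  reads$mapq, reads$end - reads$start, reads$seq, reads$nm)
  sam <- paste0(prefix, ".sam")
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Read an aligned-read BAM into the internal read table
#'
#' Loads qname, position, strand, MAPQ, sequence and the NM (edit distance)
#' tag from a BAM produced by any aligner, in the layout the scoring
#' functions consume. Secondary, supplementary, unmapped and duplicate
#' alignments are dropped.
#'
#' @param bam Path to an indexed BAM.
#' @return data.table with `qname`, `chrom`, `start` (0-based), `end`,
#'   `strand`, `mapq`, `nm`, `seq`.
#' @export
read_genome_bam <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$pos)
  wid <- Biostrings::width(b$seq)
  data.table::data.table(
    qname = b$qname, chrom = as.character(b$rname),
    start = b$pos - 1L, end = b$pos - 1L + wid,
    strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    mapq = b$mapq,
    nm = if (is.null(b$tag$NM)) rep(NA_integer_, n) else b$tag$NM,
    seq = as.character(b$seq))
}
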