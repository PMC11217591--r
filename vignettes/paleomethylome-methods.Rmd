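---
title: "Damage-based paleomethylome analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damage-based paleomethylome analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

In UDG-treated ancient DNA libraries, uracils arising from postmortem
deamination of *unmethylated* cytosines are excised, while deaminated
*methylated* cytosines survive as C→T transitions. At a CpG site, the
fraction of reads carrying T rather than C at the cytosine therefore tracks
the site's methylation level, attenuated by the (small) probability that a
given molecule was deaminated at that position at all. Writing $n_{1}$ for
deaminated and $n_{0}$ for non-deaminated read observations at a site, the
methylation score is

$$MS = \frac{n_1}{n_0 + n_1},$$

with expectation approximately $m \cdot d$, where $m$ is the true
methylation probability and $d$ the effective terminal deamination rate of
the producing library. $MS$ is thus a *relative* measure: comparable within
a genome, but scaled by a library-specific $d$ that varies multiple-fold
between laboratories. Everything downstream of scoring exists to deal with
that fact.

Deamination is concentrated at molecule termini, so only read positions
within a terminal window carry usable signal: the 5' end for double-stranded
libraries, both ends for single-stranded ones. Evidence counting
(`count_site_evidence()`) reads the base at the CpG cytosine — the C on the
forward orientation, the G one base downstream on the reverse orientation —
when it falls within `damage_window` bases of an eligible end; T/A is
deaminated, C/G is not, anything else is ignored; a read contributes at most
once per site, the 5' end winning when both ends of a single-stranded read
are eligible.

### The evidence window default

`damage_window = 20` is the package's calibration, not an arbitrary pick.
With typical aDNA fragments of mean length $L \approx 60$ bp and coverage
$c$, the expected number of evidence reads per CpG is
$\lambda \approx c\,W\,e/L$ ($e$ = number of eligible ends). Real UDG-treated
cohorts at median 9x coverage retain roughly a quarter of CpG sites at the
conventional ≥4-read evidence filter, which requires $\lambda \approx 2.4$,
i.e. $W \approx 16\textrm{–}25$. A window of 2 bp, by contrast, gives
$\lambda \approx 0.3$ and would leave essentially no site above the filter
at realistic coverages. The window is constant-rate within `damage_window`
(no decay), a deliberate simplification shared between the simulator and the
scorer; both expose the parameter.

## The synthetic cohort

The generator exists so that every stage can be validated against known
truth. It emulates, at miniature scale, the statistical structure of a
multi-laboratory UDG-treated shotgun cohort:

* **Reference** (`build_reference()`): CpG-depleted background (~1% of
  positions start a CG) with CpG-dense islands, a gene/exon table, and a SNP
  mask over a configurable fraction of CpGs.
* **Truth methylome** (`draw_truth_methylome()`): island sites
  $m \sim \mathrm{Beta}(1, 9)$ (mean 0.1), non-island sites
  $m \sim \mathrm{Beta}(8, 2)$ (mean 0.8) — hypomethylated islands against
  a 60–80% methylated background. A fraction of genes carries an additive
  subsistence effect $\delta m$ applied to the farmer group.
* **Laboratories** (`lab_profiles()`): deamination rates spread over
  0.015–0.09 so mean $MS$ spans roughly 1–6%, distinct coverages, one
  single-stranded-library lab, and a *regional damage-recovery pattern*:
  the effective $d$ varies over 10 kb regions by a lab-specific lognormal
  factor (`regional_sd`, default 0.25). The scalar part of $d$ cancels
  exactly under mean normalization; it is the lab-coherent regional pattern
  — the kind of protocol-driven coverage/recovery heterogeneity reported
  for multi-laboratory compilations — that makes profiles cluster by
  producing laboratory after normalization. Set `regional_sd = 0` for
  idealized uniform labs.
* **Reads** (`simulate_genome_reads()`): uniform fragment placement,
  discretized lognormal lengths (mean 60 bp, floored at the 35 bp filter),
  Poisson-targeted coverage halved on chrX for XY genomes, damage drawn per
  eligible CpG with probability $m \cdot d_{\text{site}}$, G→A mirrored on
  reverse-strand reads, and a truth ledger recording every eligible
  contribution. Sequencing error, indels, contamination and alignment error
  are out of scope: reads are emitted pre-aligned at their true positions.

Three generator choices deserve explicit justification:

* **Effect sign.** Subsistence effects default to farmer *hypo*methylation
  ($\delta m = -0.5$). With the non-island baseline near 0.8 and $m$ clamped
  to $[0,1]$, a positive shift of that magnitude would be mostly absorbed by
  the clamp (mean expressible shift ≈ +0.2), silently halving the nominal
  effect; a downward shift expresses it fully. `effect_sign` exposes both.
* **Effect size.** $|\delta m| = 0.5$ satisfies the detectability
  calibration $|\delta m|\cdot\bar d \ge 2\,SE_{site}$ at the default
  damage rates and read depths.
* **Coverage floor.** The default cohort preset draws per-genome coverage in
  5–30x rather than the published 1–58x range. On a reference three orders
  of magnitude smaller than a real genome, a 1x genome retains a handful of
  CpG sites by Poisson thinning alone (real 1x genomes retain thousands
  because 13 million sites are available), so the desk-scale floor keeps
  every genome statistically present without changing any per-site
  property.

Gene-level runs use references with `cpg_keep_prob` raised so genes carry a
few hundred CpGs, matching the hundreds of CpGs per gene (median ~261) that
real gene-level datasets average over; with only a dozen CpGs per miniature
gene, every gene statistic would instead be dominated by deaminated-read
scarcity noise that real gene sizes do not exhibit.

## Monte Carlo normalization

Genomes are equalized to a common pooled mean score $t$ (default 0.02,
chosen at the lower end of typical cohort means) by subsampling reads
without replacement, generalizing the factor $49 = (1-t)/t$:

* below target: retain all $N_1$ deaminated reads, draw
  $\mathrm{round}((1-t)/t \cdot N_1)$ non-deaminated reads from the pooled
  genome-wide $N_0$;
* above target: retain all non-deaminated reads, draw
  $\mathrm{round}(N_0/((1-t)/t))$ deaminated reads.

Drawing uniformly from the pooled reads allocates retained counts across
sites as a multivariate hypergeometric. Rounding is half-away-from-zero
(minimizing $|achieved - t|$); the achieved mean is within one read of the
target; genomes already within one read are left untouched. The depth
filter (≥4) is applied *before* normalization and not re-applied after, so
sites that lose all reads in a draw vanish from that replicate — which is
why replicate gene sets differ slightly. Replicates (`make_replicates()`,
conventionally 20; smaller counts in the test suite) use seeds derived
deterministically from a base seed.

**chrX.** Forcing chrX to the same fixed target per genome would equalize
the very quantity the sex analysis measures. `make_chrx_replicates()`
therefore subsamples chrX reads with the genome's *autosomal* case and
retention fraction (a deterministic function of the autosomal totals), so
that dividing the result by the genome's normalized autosomal mean
(`normalize_chrx()`) reproduces the raw chrX-over-autosome ratio on a
common scale. This resolves the ambiguity in "normalized in the same
manner, separately" in the only direction that leaves the female
X-inactivation signal observable.

## Gene datasets and the statistical battery

CpG-to-gene assignment uses the gene's exon-bounding span (a CpG may belong
to several genes); exon-only assignment is available. Two dataset shapes are
built (`build_gene_datasets()`):

1. **Full data**: per replicate, per gene, per genome, one row per CpG with
   subsampled counts — material for read-level models;
2. **Gene-averaged matrix**: per gene and genome, mean site $MS$ within a
   replicate, averaged over the replicates where the cell exists.

`fit_stratified_model()` fits the read-level binary model
`deamination ~ subsistence + tissue + sex + Error(stratum)` with
`stats::aov`, stratum `individual` or `laboratory`, sequential (Type I) sums
of squares in the stated order. Each factor is reported from the stratum
where it carries its degrees of freedom: for the individual stratum this is
the between-genome test, which is what shields the factor tests (partially)
from read-level pseudoreplication; for the laboratory stratum the factors
vary within labs and are reported from the Within stratum. Inestimable
configurations (constant response, single factor level, saturated stratum)
yield `NA` rather than errors, so tested-gene counts can differ between
models. The test suite validates the fit against a hand-coded weighted
sequential sums-of-squares decomposition on per-genome means.

The gene-averaged tests (`gene_averaged_tests()`) run one-factor-at-a-time
one-way ANOVA and Kruskal–Wallis on the matrix cells (one observation per
genome per gene — no pseudoreplication), for genes observed in at least
`min_individuals` genomes (presets 20/25/30). Benjamini–Hochberg correction
is applied per factor across genes (and per model and replicate in the
battery). Across replicates, per-replicate significant sets and their
ranges/union/intersection are reported; no meta-analytic combination is
invented.

`mds_profiles()` embeds pairwise Euclidean distances between genome
profiles (complete-case genes by default; a pairwise-complete option
rescales squared distances by shared-gene fraction) with classical MDS
(`cmdscale`), supporting outlier exclusion lists. `codirectionality()`
computes tie-aware Spearman correlation between per-gene
$\delta MS(F{-}HG)$ values and an external log fold-change table over
shared genes, with an all-pairs matrix variant that reports $r$ in the
upper and $p$ in the lower triangle.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; BED is native; exon tables
  are read in UCSC convention (0-based start, 1-based end).
* Only the forward-strand C position keys a CpG; reverse-strand G evidence
  folds onto it.
* Overlapping CGI intervals are merged before flank tiers are drawn; where
  flanks of adjacent islands meet, the nearer island assigns the tier, with
  exact ties going to the upstream island's downstream flank.
* Minus-strand promoters are mirrored (2 kb either side of the last exon
  end) rather than dropping minus-strand genes; promoters clip at
  chromosome bounds.
* Constant-response gene fits are `NA` (inestimable); constant gene-average
  vectors give $p = 1$; empty site sets are contract errors at pooling and
  explicit missing entries in matrices.
* Wilcoxon island-contrast tests are paired, one-sided
  (island < comparison class), and return $p = 1$ when all paired
  differences vanish.

## Problem sizes used by the validation suite

The shipped tests run the full pipeline at desk scale: a 34-genome default
cohort over ~0.9 Mb with 100 genes of 8 kb (subsistence-effect recovery and
island hypomethylation), a 12-genome two-laboratory cohort over ~1.1 Mb
with CpG-dense 10 kb genes (batch-effect dominance), a 12-genome null
cohort with 2000 small genes over 2.3 Mb (type-I calibration), and a
12-genome chrX cohort (sex contrast and its null). Replicate counts are
3–5 rather than 20. These sizes were chosen so that each scenario carries
the statistical power its check needs; none of the scientific defaults
(damage window, Beta truth, target 0.02, filters) change with scale.

## What passing the suite does and does not show

The generator reproduces the *statistical* structure the analysis assumes:
terminal-damage methylation readout, island hypomethylation, lab-driven
scale and pattern heterogeneity, group effects with known sign and size.
It does not model sequencing error, mapping artifacts, reference bias,
contamination, CpG→TpG germline variation beyond the SNP mask, or
evolutionary covariance between neighboring sites. Passing tests therefore
demonstrate that the pipeline measures what it claims *given aligned,
damage-bearing reads* — not that any particular biological signal is
recoverable from any particular real cohort.

One calibration worth knowing about: with 10% of genes carrying a true
effect and the remaining genes exactly null, the Spearman correlation
between measured $\delta MS$ values and a co-directional external table has
a rank-theoretic ceiling of $1 - f^3 - (1-f)^3 \approx 0.27$ at $f = 0.1$,
because null genes are rank-exchangeable in both tables regardless of
sample size. Observed values near 0.24–0.28 against a clean shared-mode
table are therefore the *expected* outcome of a perfectly working pipeline
at that DMG fraction, not an attenuation artifact.

## Interface note

The package is an R analysis toolkit: the exported functions compose the
pipeline (simulate → annotate → score → normalize → analyze), and this
vignette plus the README's worked example are the operating manual. No
shell entry point is shipped; `scripts/acceptance.R` shows the package
driven end-to-end non-interactively.
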