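---
title: "Models and methods behind karyoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscope)
```

## The problem

Immortalized cell lines accumulate chromosomal abnormalities: whole-
chromosome aneuploidy, segmental copy-number changes, hemizygous
deletions and copy-neutral loss of heterozygosity (LOH). These reshape
gene dosage and the epigenome, so any functional annotation of a cell
line has to start from its actual karyotype, not the reference diploid
assumption. karyoscope infers that karyotype from two whole-genome
sequencing evidence streams and then carries the standard epigenomic
bookkeeping — enhancer calling, replicate concordance, RRBS/WGBS
complementarity, and expression/methylation/histone-score correlation —
on top of it.

## Allele-balance and depth model

At a heterozygous site on a segment with `c` copies, `k` of which carry
one allele, the fraction of reads supporting that allele concentrates at
`k/c`; because the reference allele is equally likely to sit on either
haplotype class, a chromosome's histogram shows modes at both `k/c` and
`1 - k/c`. Diploid AB gives a single mode at 0.5, triploid AAB gives
1/3 and 2/3, AAAB gives 1/4 and 3/4, and the balanced tetraploid AABB
gives 0.5 again — which is why depth is indispensable: mean binned
coverage scales as `c/2` of the diploid baseline and is the only
evidence separating AABB from AB.

Per candidate state the classifier sums three log-likelihood terms:

* **Site term.** Each site's alternate-read count is beta-binomial
  (overdispersion `rho`, default 0.01, absorbing mapping bias) under an
  equal-weight mixture over the state's expected ratios. Monosomy/LOH
  has no heterozygous state, so observed het sites are treated as caller
  artifacts, uniform over their possible counts (`1/(n+1)` per site).
* **Depth term.** A Gaussian log-density of the chromosome's median bin
  depth around `baseline * c/2` with `sigma_d = 0.1 * baseline`,
  weighted by `w_d = 20`. The weight was chosen so a one-copy depth
  shift carries evidence comparable to a few hundred het sites, i.e.
  neither stream can silently dominate the other.
* **Het-density term** (optional, used by the genome-level wrapper). The
  observed het-site count is Poisson with the genome-wide density as
  expectation; monosomy/LOH expects 5% of it. This is what turns a het
  desert into positive evidence for copy-number-1/LOH rather than mere
  absence of evidence.

Ties break toward smaller `c` (parsimony), and calls whose margin over
the runner-up is below 10 log-units are flagged low-confidence,
mirroring the hedged "possible" language such calls deserve.

The diploid baseline itself is the kernel-density mode of the
per-chromosome median bin depths (aneuploid chromosomes are assumed the
minority), or the median over a user-declared diploid list.

```{r}
u <- uniform_karyotype(3, 1, length = 100e6, baseline_depth = 30)
sim <- simulate_wgs(u, seed = 7)
classify_chromosome_ploidy(sim$snvs,
                           median(sim$depth$depth, na.rm = TRUE),
                           baseline = 30)
```

## Segmentation and depth anomalies

Segmental changes are found on the site sequence, not on fixed windows:
each site is reduced to a Bernoulli indicator ("allele ratio within
0.15 of 0.5", i.e. looks diploid) and greedy binary segmentation
maximizes the Bernoulli log-likelihood gain, accepting splits above 15
log-units with at least 100 sites per side. Long het-free gaps (over
2 Mb, about forty-fold the expected inter-site spacing at the default
density) are split out first as desert segments and classified on depth
alone. Each segment is then re-classified with the chromosome
classifier restricted to its sites and bins, and adjacent segments with
identical states merge. Breakpoints are placed midway between flanking
sites, so localization error is bounded by the inter-site spacing.

Large deletions and duplications are read off the binned depth track:
maximal runs of bins below `0.6 x median` (loss) or above
`1.4 x median` (gain) spanning at least 1 Mb. Individual 50-kb bins are
noisy (negative-binomially overdispersed), so runs of the same kind
separated by at most 10 non-anomalous bins are bridged before applying
the length gate, and a merged region is kept only if its own mean depth
passes the threshold. Zero-coverage bins are excluded from medians
rather than imputed.

## The enhancer rule and peak concordance

Enhancers are H3K27ac peaks farther than 1000 bp from every H3K4me3
peak. "Within 1000 bp" is read edge-to-edge: an overlap is distance 0
and a gap of exactly 1000 bp still counts as within, so such a peak is
removed — the most permissive reading that still excludes
promoter-proximal H3K27ac. The rule is idempotent and anti-monotone in
the distance, both tested.

Replicate concordance counts peaks overlapping by at least 1 bp (the
sources give no minimum overlap fraction) and reports two Pearson
correlations: mean read coverage of the two replicates over the merged
intersection regions, and signal values over 1-to-1 matched overlapping
pairs, where a peak overlapping several partners is matched to the one
with the largest overlap. Both directions of the overlap count are
reported because "peaks of A in B" and "peaks of B in A" genuinely
differ.

## Methylation and RRBS/WGBS complementarity

Per-context summaries (CpG/CHG/CHH) use unweighted means over sites
with at least 10 reads; a context with no surviving site is missing,
not zero. RRBS-exclusive sites are RRBS records with coverage >= 10
whose position is absent from WGBS or present below 10 reads.
Complementary-strand CpGs are distinct positions by default (matching
per-cytosine records); an optional strand merge sums counts onto the
plus-strand cytosine of the dyad. Exclusive sites merge into regions at
a 200-bp gap — CpG-island scale, chosen here as no merging distance is
standard — and regions are annotated with every regulatory category
(promoter = H3K4me3 peaks, enhancer = the rule above) they intersect.

## Integrative analysis

TPM is cut into five right-closed classes at 1, 5, 20 and 100: the
outer bounds are the conventional "expressed" and "very high"
thresholds, the interior bounds are package defaults and configurable.
Per gene, methylation is averaged over covered CpGs in the TSS window
(+/- 1 kb) and in the gene body — defined as the transcribed span minus
the TSS window, the simplest definition that avoids double-counting
promoter CpGs. Peak scores take the maximum over peaks within +/- 2 kb
of the TSS (robust to sub-peak splitting), zero when none. Correlations
are pairwise-complete Pearson (the assays have different missingness),
requiring at least 3 complete pairs per entry. The per-chromosome
dosage comparison filters to TPM > 2, summarizes medians and quartiles,
and uses a Wilcoxon rank-sum test with a median-ratio effect size — a
nonparametric choice matching the boxplot-level claim it supports.

## The synthetic genome

The simulator is the package's test bed: it emulates exactly the
statistical structure the estimators assume, with truth labels.

* **WGS**: per-50-kb-bin depth is negative-binomial with mean
  `baseline * c/2` (size 100, mild overdispersion — real WGS bins are
  overdispersed relative to Poisson); het sites are a Poisson process
  (default one per 50 kb) on segments with a heterozygous configuration;
  alternate counts are beta-binomial (`rho = 0.01`) at `k/c` or
  `1 - k/c` with equal probability (reference-allele phasing).
  Monosomic and LOH segments emit no het sites.
* **Expression**: 20,000 genes, 66% fully silent, the rest log-normal
  (`sdlog = 1.5`), scaled by `(c/2)^dosage_exponent` (default 1,
  proportional dosage — no quantitative dosage-effect size is
  established, so proportionality is the neutral choice) and
  renormalized to sum to 1e6. The silent fraction mirrors the roughly
  one-third-expressed proportion of real transcriptomes and is what
  makes the renormalized table span all five expression classes at this
  gene count; dosage effects survive only as relative shifts between
  chromosomes, exactly as in real TPM.
* **Epigenome**: active promoters draw H3K4me3 (and, only where K4me3
  is present, H3K27ac) with probability and signal rising in log TPM;
  silent genes get an H3K27me3 domain and no promoter marks; truth
  enhancers are distal H3K27ac-only peaks placed at least 2 kb from any
  TSS, so the 1000-bp rule recovers them exactly. TSS CpG methylation
  falls with log TPM (the canonical inverse promoter relationship);
  the gene-body trend has a configurable sign (positive by default —
  a slight rise with expression, as seen in mammalian somatic tissue —
  negative available for lineages where the opposite holds). RRBS
  covers promoters at ~70x and a sparse 20% of gene bodies; WGBS covers
  everything at ~30x except a configurable 10% of promoter CpGs left
  below 10x — the truth RRBS-exclusive set.

Default karyotype presets bundle the abnormality patterns of interest:
mostly diploid with one whole trisomy, one chromosome with a distal
4:AAAB segment, one with a monosomic proximal half (het desert) plus
4:AAAB distal half, one diploid chromosome with an 8-Mb hemizygous
deletion at 9-17 Mb; the second preset adds a whole balanced
tetraploid chromosome.

What the simulator does **not** emulate: sequence content and mapping
artifacts (GC waves, repeats, allele-specific mapping loss beyond the
flat beta-binomial), structural-variant breakpoints, subclonal mixtures,
replication-timing coverage trends, and assay-specific methylation
biases. Passing tests therefore demonstrate correctness of the
estimators under their stated model, not robustness to every real-data
pathology.

## Numerical choices and problem sizes

Simulated checks run at desk scale, chosen to keep the full suite in
minutes while leaving comfortable statistical margins: 10,000 sites for
mode location (KDE with fixed bandwidth 0.025, the granularity of count
ratios at 30-60x, so discreteness is smoothed without merging modes a
copy-number step apart); 200 chromosomes at 2,000 sites and 30x for
state recovery; 50 replicate seeds for breakpoint localization; 20
seeds for the integrative sign pattern. The beta-binomial density is
computed in log space from `lchoose` and `lbeta` and is verified in the
tests against an independent numerical Beta integral at 1e-9.

## Known limitations

* The candidate set stops at `c = 4` by default; higher ploidies would
  need both the candidate table (one line of config) and a depth model
  re-check, since `sigma_d` proportional to the baseline grows slack at
  high `c`.
* Copy-neutral LOH and monosomy are separated only by depth; with a
  noisy or missing depth track both collapse into the het-desert call.
* Breakpoint localization is limited by het-site spacing; in deserts it
  falls back to bin resolution.
* The concordance coverage correlation depends on the supplied depth
  tracks' binning; very coarse tracks blur region means.
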