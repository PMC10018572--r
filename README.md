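# karyoscope

Karyotype and epigenome characterization of immortalized cell lines
from whole-genome sequencing, ChIP-seq, bisulfite and RNA-seq data.

Cell lines drift from the karyotype of their tissue of origin —
whole-chromosome and segmental aneuploidy, hemizygous deletions and
loss of heterozygosity are the rule — and those changes reshape gene
dosage and the epigenome. karyoscope provides the computations needed
to characterize such a line:

* **Ploidy inference.** At a heterozygous site on a segment with *c*
  copies, *k* carrying one allele, the allele-support ratio concentrates
  at *k/c* and *1 − k/c*: 0.5 for diploid AB, 1/3 and 2/3 for triploid
  AAB, 1/4 and 3/4 for AAAB, and 0.5 again for balanced tetraploid AABB
  (separated from diploidy only by depth, which scales as *c/2* of the
  diploid baseline). A beta-binomial mixture over these ratios, a
  Gaussian term on median bin depth, and a Poisson term on het-site
  density are combined into a per-chromosome (and per-segment) maximum
  likelihood state call with a log-likelihood confidence margin.
* **Segmentation and anomalies.** Binary segmentation of the per-site
  "looks diploid" indicator finds segmental aneuploidy; het-free
  deserts are split out and classified on depth (monosomy/LOH); runs of
  low/high 50-kb depth bins flag large deletions and duplications.
* **Peak analysis.** The distance rule for enhancers (H3K27ac peaks
  farther than 1000 bp from every H3K4me3 peak), replicate concordance
  (overlap counts, coverage and signal correlations), TSS mark
  enrichment, and chromosome-size-normalized event rates.
* **Methylome.** Per-context (CpG/CHG/CHH) summaries at a coverage
  floor, RRBS-vs-WGBS complementarity (sites the reduced-representation
  assay covers at ≥ 10× that WGBS misses), merging into regions,
  regulatory overlay.
* **Integration.** Per-gene feature table (TPM, expression class, TSS
  and gene-body methylation, per-mark peak scores), pairwise-complete
  correlation matrices, and per-chromosome dosage-expression shift
  tests.
* **A truth-labelled simulator** generating all of the above with known
  karyotype, expression and epigenome ground truth, used throughout the
  test suite.

## Worked example

Simulate a mostly diploid genome with one trisomy (chr5), a distal
4:AAAB segment on chr2, a monosomic proximal half on chr3 and an 8-Mb
deletion on chr4, then call everything back:

```r
library(karyoscope)

spec <- karyotype_preset("ipecj2")
sim  <- simulate_wgs(spec, seed = 1)
calls <- call_ploidy_genome(sim$snvs, sim$depth)
calls[, c("chromosome", "best_state", "confidence", "depth_ratio",
          "het_density", "n_sites")]
#>   chromosome best_state confidence depth_ratio het_density n_sites
#> 1       chr1       2:AB       1003       0.998       20.52    2463
#> 2       chr2      3:AAB       1585       1.198       19.57    1957
#> 3       chr3      3:AAB        191       1.032        9.75     780
#> 4       chr4       2:AB        877       0.932       17.38    1043
#> 5       chr5      3:AAB        849       1.498       20.10    1206
```

chr1 and chr4 are diploid; chr5 is the trisomy (depth ratio 1.50, i.e.
3 copies). chr2 and chr3 are *mixtures*, so the whole-chromosome call
is a compromise — segmentation resolves them:

```r
segment_allele_ratio(sim$snvs[sim$snvs$chromosome == "chr2", ],
                     binned   = sim$depth[sim$depth$chromosome == "chr2", ],
                     baseline = attr(calls, "baseline"),
                     chrom_length = 100e6)
#>   chromosome    start       end  state n_sites mean_depth low_confidence
#> 1       chr2        1  60010025   2:AB    1209         30          FALSE
#> 2       chr2 60010026 100000000 4:AAAB     748         60          FALSE
```

The diploid-to-AAAB breakpoint is placed 10 kb from the simulated truth
at 60 Mb. The deletion on chr4 (truth: 9–17 Mb at copy number 1):

```r
detect_depth_anomalies(sim$depth[sim$depth$chromosome == "chr4", ])
#>   chromosome   start      end mean_depth kind
#> 1       chr4 8700001 16900000      15.61 loss
```

Real data enter through the readers: `read_vcf_allele_depths()` (GT/AD
fields), `read_depth_bedgraph()` + `bin_depth()`, `read_peaks()`
(narrowPeak/broadPeak/BED3), `read_methylation_table()` (CGmap), and
`read_gtf_genes()` + `read_expression_tsv()`. A command-line front end
covering the same pipeline lives at `inst/cli/karyoscope.R`
(subcommands `simulate`, `ploidy`, `enhancers`, `concord`, `methyl`,
`integrate`).

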