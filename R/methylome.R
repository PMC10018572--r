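## Methylation summaries by sequence context, RRBS-vs-WGBS coverage
## complementarity, and regulatory annotation of RRBS-exclusive regions.

#' Per-context methylation summary
#'
#' Mean methylation level per sequence context (CpG, CHG, CHH) over sites
#' with sufficient coverage. Means are unweighted across sites; a context
#' with no surviving site is reported as NA, not 0.
#'
#' @param sites methylation data.frame ([read_methylation_table()] layout)
#' @param min_cov minimum total reads per site (sites below are dropped as
#'   uninformative)
#' @return data.frame `context`, `mean_level`, `n_sites` with one row per
#'   context
#' @export
context_summary <- function(sites, min_cov = 10) {
  keep <- sites[sites$total_reads >= min_cov, , drop = FALSE]
  contexts <- c("CpG", "CHG", "CHH")
  mean_level <- vapply(contexts, function(ctx) {
    lv <- keep$level[keep$context == ctx]
    if (length(lv) == 0) NA_real_ else mean(lv)
  }, 0)
  n_sites <- vapply(contexts, function(ctx) sum(keep$context == ctx), 0L)
  data.frame(context = contexts, mean_level = unname(mean_level),
             n_sites = unname(n_sites), stringsAsFactors = FALSE)
}

#' Merge complementary-strand CpG records
#'
#' CpG sites called on the minus strand are mapped to the plus-strand
#' cytosine of the same CpG dyad (position - 1) and read counts summed
#' with any plus-strand record there.
#'
#' @param sites methylation data.frame
#' @return strand-merged data.frame (strand set to "+")
#' @export
merge_strands <- function(sites) {
  cpg <- sites$context == "CpG"
  pos <- sites$position
  pos[cpg & sites$strand == "-"] <- pos[cpg & sites$strand == "-"] - 1
  key <- paste(sites$chromosome, pos, sites$context, sep = "\r")
  meth <- tapply(sites$methylated_reads, key, sum)
  tot <- tapply(sites$total_reads, key, sum)
  parts <- strsplit(names(meth), "\r", fixed = TRUE)
  out <- data.frame(
    chromosome = vapply(parts, `[`, "", 1),
    position = as.numeric(vapply(parts, `[`, "", 2)),
    strand = "+",
    context = vapply(parts, `[`, "", 3),
    methylated_reads = as.numeric(meth),
    total_reads = as.numeric(tot),
    stringsAsFactors = FALSE)
  out$level <- out$methylated_reads / out$total_reads
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sites covered by RRBS but not (adequately) by WGBS
#'
#' Returns the RRBS sites, in the requested contexts and with coverage at
#' least `min_cov`, whose position is either absent from the WGBS table or
#' present with WGBS coverage below `min_cov` — the complementarity
#' question of whether the reduced-representation assay sees cytosines the
#' whole-genome assay misses.
#'
#' @param rrbs,wgbs methylation data.frames from the same assembly
#' @param min_cov informative-coverage threshold applied to both assays
#' @param contexts contexts considered (default CpG only)
#' @param merge_strand_cpg merge complementary-strand CpGs before
#'   comparing positions
#' @return the exclusive subset of `rrbs`
#' @export
rrbs_exclusive_sites <- function(rrbs, wgbs, min_cov = 10,
                                 contexts = "CpG",
                                 merge_strand_cpg = FALSE) {
  if (merge_strand_cpg) {
    rrbs <- merge_strands(rrbs)
    wgbs <- merge_strands(wgbs)
  }
  cand <- rrbs[rrbs$total_reads >= min_cov &
                 rrbs$context %in% contexts, , drop = FALSE]
  wg_ok <- wgbs[wgbs$total_reads >= min_cov &
                  wgbs$context %in% contexts, , drop = FALSE]
  key <- function(df) paste(df$chromosome, df$position, df$strand)
  out <- cand[!key(cand) %in% key(wg_ok), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby sites into regions
#'
#' Consecutive sites on the same chromosome separated by at most
#' `max_gap` bp are merged into one region; a lone site becomes a 1-bp
#' region.
#'
#' @param sites methylation data.frame (sorted by chromosome, position)
#' @param max_gap maximum inter-site gap in bp
#' @return data.frame `chromosome`, `start`, `end`, `n_sites`,
#'   `mean_level`
#' @export
merge_sites_to_regions <- function(sites, max_gap = 200) {
  if (nrow(sites) == 0) {
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_sites = integer(),
                      mean_level = numeric(), stringsAsFactors = FALSE))
  }
  sites <- sites[order(sites$chromosome, sites$position), , drop = FALSE]
  new_chrom <- c(TRUE, sites$chromosome[-1] != sites$chromosome[-nrow(sites)])
  gap <- c(Inf, diff(sites$position))
  grp <- cumsum(new_chrom | gap > max_gap)
  out <- lapply(split(sites, grp), function(d) {
    data.frame(chromosome = d$chromosome[1], start = min(d$position),
               end = max(d$position), n_sites = nrow(d),
               mean_level = mean(d$level), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate regions with the regulatory elements they intersect
#'
#' @param regions region data.frame from [merge_sites_to_regions()]
#' @param promoters promoter intervals (typically the H3K4me3 peak set)
#' @param enhancers enhancer intervals (from [call_enhancers()])
#' @return `regions` with logical columns `promoter`, `enhancer` and a
#'   combined `annotation` string ("promoter", "enhancer",
#'   "promoter,enhancer" or "none"); per-category counts in the
#'   `"category_counts"` attribute
#' @export
overlay_regulatory <- function(regions, promoters, enhancers) {
  rg <- GenomicRanges::GRanges(regions$chromosome,
                               IRanges::IRanges(regions$start, regions$end))
  hit_prom <- if (nrow(promoters) > 0) {
    IRanges::overlapsAny(rg, peaks_gr(promoters))
  } else rep(FALSE, length(rg))
  hit_enh <- if (nrow(enhancers) > 0) {
    IRanges::overlapsAny(rg, peaks_gr(enhancers))
  } else rep(FALSE, length(rg))
  regions$promoter <- hit_prom
  regions$enhancer <- hit_enh
  regions$annotation <- ifelse(
    hit_prom & hit_enh, "promoter,enhancer",
    ifelse(hit_prom, "promoter", ifelse(hit_enh, "enhancer", "none")))
  attr(regions, "category_counts") <- c(
    promoter = sum(hit_prom), enhancer = sum(hit_enh),
    none = sum(!hit_prom & !hit_enh))
  regions
}
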