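## Peak-set computations: the H3K27ac/H3K4me3 distance rule for enhancer
## identification, replicate concordance, TSS mark enrichment, and
## per-chromosome rate normalization.

peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chromosome,
                         IRanges::IRanges(peaks$start, peaks$end))
}

#' Identify enhancers by the H3K27ac / H3K4me3 distance rule
#'
#' An enhancer is an H3K27ac peak that is not within `distance` bp of any
#' H3K4me3 peak: peaks whose edge-to-edge gap to every H3K4me3 peak
#' exceeds the distance are retained (an overlap counts as gap 0, and a
#' gap of exactly `distance` is still "within", so the peak is removed).
#'
#' @param h3k27ac H3K27ac peak data.frame (sorted)
#' @param h3k4me3 H3K4me3 peak data.frame (sorted)
#' @param distance promoter-proximity threshold in bp
#' @return the retained subset of `h3k27ac`, order preserved
#' @export
call_enhancers <- function(h3k27ac, h3k4me3, distance = 1000) {
  if (nrow(h3k27ac) == 0) return(h3k27ac)
  if (nrow(h3k4me3) == 0) return(h3k27ac)
  a <- peaks_gr(h3k27ac)
  b <- peaks_gr(h3k4me3)
  # chromosomes private to one set are fine: distance stays NA there
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(a, b))
  gap <- rep(NA_real_, length(a))
  gap[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  keep <- is.na(gap) | gap > distance   # NA: no H3K4me3 on that chromosome
  out <- h3k27ac[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Coverage-weighted mean depth of a track over query intervals.
track_mean_depth <- function(track, gr) {
  tr <- GenomicRanges::GRanges(track$chromosome,
                               IRanges::IRanges(track$start, track$end))
  hits <- GenomicRanges::findOverlaps(gr, tr)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(tr)[S4Vectors::subjectHits(hits)]))
  num <- tapply(w * track$depth[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  den <- tapply(w, S4Vectors::queryHits(hits), sum)
  out <- rep(NA_real_, length(gr))
  out[as.integer(names(num))] <- num / den
  out
}

#' Replicate concordance of two peak sets
#'
#' Counts peaks of each set overlapping the other (>= 1 bp), and, over the
#' overlap, two Pearson correlations: read-coverage correlation of the
#' merged intersection regions (mean depth of each replicate's track over
#' each region) and signal-value correlation of 1-to-1 matched overlapping
#' peak pairs (each peak of `a` matched to its largest-overlap partner in
#' `b`). With fewer than two overlapping regions/pairs the correlations
#' are reported as NA.
#'
#' @param a,b peak data.frames
#' @param coverage_a,coverage_b optional depth tracks for the two
#'   replicates (needed for the coverage correlation)
#' @return list of class `concordance_report`: `n_a`, `n_b`,
#'   `n_overlapping` (peaks of a overlapping b), `n_overlapping_b`,
#'   `coverage_correlation`, `signal_correlation`
#' @export
replicate_concordance <- function(a, b, coverage_a = NULL,
                                  coverage_b = NULL) {
  ga <- peaks_gr(a)
  gb <- peaks_gr(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_overlapping <- length(unique(qh))
  n_overlapping_b <- length(unique(sh))

  coverage_correlation <- NA_real_
  if (!is.null(coverage_a) && !is.null(coverage_b) && length(hits) > 0) {
    inter <- GenomicRanges::reduce(GenomicRanges::pintersect(ga[qh], gb[sh]))
    if (length(inter) >= 2) {
      ca <- track_mean_depth(coverage_a, inter)
      cb <- track_mean_depth(coverage_b, inter)
      ok <- !is.na(ca) & !is.na(cb)
      if (sum(ok) >= 2) {
        coverage_correlation <- stats::cor(ca[ok], cb[ok])
      }
    }
  }

  signal_correlation <- NA_real_
  if (length(hits) > 0 && "signal_value" %in% names(a) &&
      "signal_value" %in% names(b)) {
    ov_w <- IRanges::width(GenomicRanges::pintersect(ga[qh], gb[sh]))
    best <- tapply(seq_along(qh), qh, function(i) i[which.max(ov_w[i])])
    qi <- qh[unlist(best)]
    si <- sh[unlist(best)]
    sa <- a$signal_value[qi]
    sb <- b$signal_value[si]
    ok <- !is.na(sa) & !is.na(sb)
    if (sum(ok) >= 2 && stats::sd(sa[ok]) > 0 && stats::sd(sb[ok]) > 0) {
      signal_correlation <- stats::cor(sa[ok], sb[ok])
    } else if (sum(ok) >= 2) {
      signal_correlation <- NA_real_
    }
  }

  structure(list(n_a = nrow(a), n_b = nrow(b),
                 n_overlapping = n_overlapping,
                 n_overlapping_b = n_overlapping_b,
                 coverage_correlation = coverage_correlation,
                 signal_correlation = signal_correlation),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("peak replicate concordance\n",
      " peaks: ", x$n_a, " vs ", x$n_b, "\n",
      " overlapping (a in b): ", x$n_overlapping,
      "; (b in a): ", x$n_overlapping_b, "\n",
      " coverage correlation:  ", format(x$coverage_correlation, digits = 3),
      "\n  signal correlation:    ", format(x$signal_correlation, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Fraction of expressed genes with a peak near the TSS
#'
#' @param peaks peak data.frame
#' @param genes gene data.frame carrying TPM
#' @param window half-width of the TSS window in bp
#' @param min_tpm expression threshold (genes with TPM > min_tpm count)
#' @return fraction in [0, 1]
#' @export
tss_mark_fraction <- function(peaks, genes, window = 1000, min_tpm = 1) {
  expressed <- genes[!is.na(genes$tpm) & genes$tpm > min_tpm, , drop = FALSE]
  if (nrow(expressed) == 0) stop("no expressed genes above min_tpm")
  tss <- GenomicRanges::GRanges(
    expressed$chromosome,
    IRanges::IRanges(pmax(1, expressed$tss - window), expressed$tss + window))
  if (nrow(peaks) == 0) return(0)
  mean(IRanges::overlapsAny(tss, peaks_gr(peaks)))
}

#' Per-chromosome event rate normalized for chromosome size
#'
#' @param items data.frame with a `chromosome` column (intervals or point
#'   events)
#' @param layout [genome_layout()] providing the length denominators
#' @return data.frame `chromosome`, `count`, `rate_per_mb` (every layout
#'   chromosome reported, zero-count included)
#' @export
per_chromosome_rate <- function(items, layout) {
  unknown <- setdiff(unique(items$chromosome), layout$chromosome)
  if (length(unknown) > 0) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(items$chromosome, levels = layout$chromosome))
  data.frame(chromosome = layout$chromosome,
             count = as.integer(counts),
             rate_per_mb = as.numeric(counts) / (layout$length / 1e6),
             stringsAsFactors = FALSE)
}
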