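## Ploidy and segmental copy-number inference from two WGS evidence
## streams: binned read depth (scales with c/2) and the allele-support
## ratio at heterozygous sites (modes at k/c and 1 - k/c for a segment
## with c copies, k of them carrying the alternate allele).

#' Expected allele-support ratios for a copy configuration
#'
#' A segment with c total copies of which k carry one allele places the
#' allele-support ratio of heterozygous sites at k/c and 1 - k/c: 0.5 for
#' a diploid AB, 1/3 and 2/3 for a triploid AAB, 1/4 and 3/4 for AAAB,
#' 0.5 again for the balanced tetraploid AABB. Configurations without a
#' heterozygous state (k = 0 or k = c, or fewer than two copies) have no
#' expected ratios.
#'
#' @param total_copies copy number c (>= 0)
#' @param alt_copies copies carrying the alternate allele, 0 <= k <= c
#' @return sorted numeric vector of expected ratios (possibly empty)
#' @export
expected_allele_ratios <- function(total_copies, alt_copies) {
  if (alt_copies > total_copies || alt_copies < 0 || total_copies < 0) {
    stop("alt_copies must lie in [0, total_copies]")
  }
  if (total_copies < 2 || alt_copies == 0 || alt_copies == total_copies) {
    return(numeric(0))
  }
  sort(unique(c(alt_copies / total_copies, 1 - alt_copies / total_copies)))
}

#' Default candidate copy-number states
#'
#' Monosomy plus the heterozygous configurations up to tetraploidy:
#' 2:AB, 3:AAB, 4:AAAB, 4:AABB. Extend by passing `max_copies` or by
#' building the data.frame directly.
#'
#' @param max_copies largest copy number considered (default 4, the
#'   highest ploidy the evidence streams here are expected to resolve)
#' @return data.frame `label`, `total_copies`, `alt_copies`
#' @export
candidate_states <- function(max_copies = 4) {
  stopifnot(max_copies >= 1)
  rows <- list(data.frame(label = "1", total_copies = 1, alt_copies = 0,
                          stringsAsFactors = FALSE))
  for (c_tot in 2:max_copies) {
    for (k in seq_len(floor(c_tot / 2))) {
      rows[[length(rows) + 1]] <- data.frame(
        label = state_label(c_tot, k), total_copies = c_tot,
        alt_copies = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[out$total_copies <= max_copies, , drop = FALSE]
}

#' Likelihood weights for ploidy classification
#'
#' @param baseline diploid baseline depth (sets the depth-noise scale)
#' @param rho beta-binomial overdispersion of allele counts
#' @param sigma_d standard deviation of the median-depth term
#' @param w_d weight of the depth log-density; the default makes a
#'   one-copy depth shift carry evidence comparable to several hundred
#'   het sites
#' @param monosomy_density_frac expected het density on a monosomic/LOH
#'   segment as a fraction of the genome-wide density (residual caller
#'   errors)
#' @return named list
#' @export
ploidy_weights <- function(baseline = NULL, rho = 0.01,
                           sigma_d = if (is.null(baseline)) NULL
                                     else 0.1 * baseline,
                           w_d = 20, monosomy_density_frac = 0.05) {
  list(rho = rho, sigma_d = sigma_d, w_d = w_d,
       monosomy_density_frac = monosomy_density_frac)
}

#' Site log-likelihood of allele counts under a copy configuration
#'
#' Sum over sites of the log equal-weight beta-binomial mixture across the
#' configuration's expected ratios. For configurations with no
#' heterozygous state (monosomy/LOH) each observed het site is treated as
#' a caller artifact, uniform over its possible allele counts.
#'
#' @param alt_reads,total_reads per-site counts
#' @param ratios expected allele ratios (possibly empty)
#' @param rho beta-binomial overdispersion
#' @return scalar log-likelihood
#' @export
site_log_likelihood <- function(alt_reads, total_reads, ratios, rho = 0.01) {
  if (length(alt_reads) == 0) return(0)
  if (length(ratios) == 0) {
    return(sum(-log(total_reads + 1)))
  }
  per_ratio <- vapply(ratios, function(r) {
    dbetabinom(alt_reads, total_reads, r, rho, log = TRUE)
  }, numeric(length(alt_reads)))
  per_ratio <- matrix(per_ratio, nrow = length(alt_reads))
  mx <- apply(per_ratio, 1, max)
  sum(mx + log(rowMeans(exp(per_ratio - mx))))
}

#' Classify the ploidy state of one chromosome (or segment)
#'
#' Combines three evidence streams per candidate state: the beta-binomial
#' mixture likelihood of the allele-support counts, a weighted Gaussian
#' log-density of the median bin depth around `baseline * c/2`, and
#' (when a genome-wide het density is supplied) a Poisson log-likelihood
#' of the observed het-site count, with monosomy/LOH expecting a small
#' fraction of the genome-wide density. Ties are broken toward smaller
#' copy number (parsimony).
#'
#' @param records allele-balance data.frame (columns `alt_reads`,
#'   `ref_reads`); may have zero rows
#' @param median_depth median bin depth of the chromosome (NA to skip the
#'   depth term)
#' @param baseline diploid baseline depth
#' @param candidates data.frame from [candidate_states()]
#' @param weights list from [ploidy_weights()]
#' @param span_bp spanned length in bp (needed for the het-density term)
#' @param expected_het_density genome-wide het density (sites/bp); NULL
#'   disables the het-count term
#' @return list of class `ploidy_call`: `best_state`, `log_likelihoods`,
#'   `confidence` (best minus runner-up), `median_bin_depth`,
#'   `depth_ratio_to_baseline`, `het_density` (sites/Mb), `n_sites`,
#'   `low_confidence`
#' @export
classify_chromosome_ploidy <- function(records, median_depth, baseline,
                                       candidates = candidate_states(),
                                       weights = ploidy_weights(baseline),
                                       span_bp = NULL,
                                       expected_het_density = NULL) {
  stopifnot(is.null(baseline) || baseline > 0)
  n_sites <- if (is.null(records)) 0 else nrow(records)
  if (is.null(median_depth)) median_depth <- NA_real_
  if (n_sites == 0 && is.na(median_depth)) {
    return(structure(list(best_state = "unknown",
                          log_likelihoods = NULL, confidence = NA_real_,
                          median_bin_depth = NA_real_,
                          depth_ratio_to_baseline = NA_real_,
                          het_density = 0, n_sites = 0,
                          low_confidence = TRUE),
                     class = "ploidy_call"))
  }
  if (is.null(weights$sigma_d) && !is.null(baseline)) {
    weights$sigma_d <- 0.1 * baseline
  }
  # order by copy number so which.max resolves ties toward smaller c
  candidates <- candidates[order(candidates$total_copies,
                                 candidates$alt_copies), , drop = FALSE]
  ll <- vapply(seq_len(nrow(candidates)), function(i) {
    c_tot <- candidates$total_copies[i]
    ratios <- expected_allele_ratios(c_tot, candidates$alt_copies[i])
    l <- site_log_likelihood(records$alt_reads,
                             records$ref_reads + records$alt_reads,
                             ratios, weights$rho)
    if (!is.null(baseline) && !is.na(median_depth)) {
      l <- l + weights$w_d *
        stats::dnorm(median_depth, baseline * c_tot / 2,
                     weights$sigma_d, log = TRUE)
    }
    if (!is.null(expected_het_density) && !is.null(span_bp)) {
      lambda <- expected_het_density * span_bp *
        if (length(ratios) > 0) 1 else weights$monosomy_density_frac
      l <- l + stats::dpois(n_sites, max(lambda, 1e-9), log = TRUE)
    }
    l
  }, 0)
  names(ll) <- candidates$label
  best <- which.max(ll)
  confidence <- if (length(ll) > 1) ll[best] - max(ll[-best]) else Inf
  structure(list(
    best_state = candidates$label[best],
    log_likelihoods = ll,
    confidence = unname(confidence),
    median_bin_depth = median_depth,
    depth_ratio_to_baseline = if (is.null(baseline)) NA_real_
                              else median_depth / baseline,
    het_density = if (is.null(span_bp)) NA_real_
                  else n_sites / (span_bp / 1e6),
    n_sites = n_sites,
    low_confidence = unname(confidence) < 10
  ), class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("ploidy call:", x$best_state,
      if (isTRUE(x$low_confidence)) "(possible / low confidence)" else "",
      "\n  confidence (log-lik margin):", format(x$confidence, digits = 4),
      "\n  median bin depth:", format(x$median_bin_depth, digits = 4),
      " depth ratio:", format(x$depth_ratio_to_baseline, digits = 3),
      "\n  het sites:", x$n_sites, "\n")
  invisible(x)
}

#' Rebin a depth track into fixed-width bins
#'
#' Each output bin's depth is the coverage-weighted mean of the input
#' intervals overlapping it; a trailing partial bin is averaged over its
#' own covered width. Bins with no covered bases get NA depth.
#'
#' @param track depth data.frame (`chromosome`, `start`, `end`, `depth`,
#'   1-based closed), intervals sorted and non-overlapping per chromosome
#' @param bin_size bin width in bp (default 50 kb, the scale used for
#'   whole-genome depth display)
#' @param chrom_lengths optional named vector of chromosome lengths; by
#'   default binning stops at the last covered base
#' @return data.frame `chromosome`, `start`, `end`, `depth`
#' @export
bin_depth <- function(track, bin_size = 50000, chrom_lengths = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  out <- lapply(split(track, track$chromosome), function(tr) {
    chrom <- tr$chromosome[1]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(tr$end)
    }
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    bins <- IRanges::IRanges(starts, ends)
    iv <- IRanges::IRanges(tr$start, tr$end)
    hits <- IRanges::findOverlaps(bins, iv)
    w <- IRanges::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(hits)], iv[S4Vectors::subjectHits(hits)]))
    num <- tapply(w * tr$depth[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    depth <- rep(NA_real_, length(bins))
    depth[as.integer(names(num))] <- num / den
    data.frame(chromosome = chrom, start = starts, end = ends,
               depth = depth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Estimate the diploid baseline depth
#'
#' The per-chromosome median bin depths are summarized to a single diploid
#' reference: the median over a supplied list of known-diploid
#' chromosomes, or — when none is given — the kernel-density mode of the
#' per-chromosome medians (aneuploid chromosomes are assumed to be the
#' minority, so the densest cluster of medians is diploid).
#'
#' @param binned binned depth data.frame from [bin_depth()]
#' @param prior_diploid optional character vector of chromosomes known to
#'   be diploid
#' @return scalar baseline depth
#' @export
diploid_baseline <- function(binned, prior_diploid = NULL) {
  meds <- tapply(binned$depth, binned$chromosome,
                 stats::median, na.rm = TRUE)
  meds <- meds[!is.na(meds)]
  if (length(meds) == 0) stop("no depth data to estimate a baseline from")
  if (!is.null(prior_diploid)) {
    keep <- names(meds) %in% prior_diploid
    if (!any(keep)) stop("none of the prior diploid chromosomes has depth")
    return(unname(stats::median(meds[keep])))
  }
  if (length(meds) < 3) return(unname(stats::median(meds)))
  d <- stats::density(meds, bw = "nrd0")
  unname(d$x[which.max(d$y)])
}

#' Classify every chromosome of a genome
#'
#' Convenience wrapper: bins are summarized per chromosome, the diploid
#' baseline estimated (unless given), the genome-wide het density taken as
#' the median per-chromosome density, and each chromosome classified with
#' [classify_chromosome_ploidy()].
#'
#' @param snvs allele-balance data.frame (all chromosomes)
#' @param binned binned depth data.frame
#' @param baseline diploid baseline; estimated when NULL
#' @param candidates,weights see [classify_chromosome_ploidy()]
#' @return data.frame with one row per chromosome: `chromosome`,
#'   `best_state`, `confidence`, `low_confidence`, `median_bin_depth`,
#'   `depth_ratio`, `het_density`, `n_sites`, plus one `logL_<state>`
#'   column per candidate
#' @export
call_ploidy_genome <- function(snvs, binned, baseline = NULL,
                               candidates = candidate_states(),
                               weights = NULL) {
  chroms <- sort(unique(binned$chromosome))
  if (is.null(baseline)) baseline <- diploid_baseline(binned)
  if (is.null(weights)) weights <- ploidy_weights(baseline)
  spans <- tapply(binned$end, binned$chromosome, max)
  n_by_chrom <- table(factor(snvs$chromosome, levels = chroms))
  density_by_chrom <- as.numeric(n_by_chrom) / as.numeric(spans[chroms])
  genome_density <- stats::median(density_by_chrom)
  rows <- lapply(chroms, function(chrom) {
    rec <- snvs[snvs$chromosome == chrom, , drop = FALSE]
    med <- stats::median(binned$depth[binned$chromosome == chrom],
                         na.rm = TRUE)
    call <- classify_chromosome_ploidy(
      rec, med, baseline, candidates, weights,
      span_bp = as.numeric(spans[[chrom]]),
      expected_het_density = genome_density)
    ll <- as.list(call$log_likelihoods)
    names(ll) <- paste0("logL_", names(ll))
    cbind(data.frame(chromosome = chrom, best_state = call$best_state,
                     confidence = call$confidence,
                     low_confidence = call$low_confidence,
                     median_bin_depth = call$median_bin_depth,
                     depth_ratio = call$depth_ratio_to_baseline,
                     het_density = call$het_density,
                     n_sites = call$n_sites, stringsAsFactors = FALSE),
          data.frame(ll, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  out
}

## Greedy binary segmentation of a Bernoulli indicator sequence.
## Returns split indices (last index of the left part). The gain of a
## split is the Bernoulli log-likelihood improvement; splits below
## min_gain or producing parts shorter than min_size are rejected.
binseg_bernoulli <- function(z, min_size, min_gain) {
  bern_ll <- function(s, n) {
    if (n == 0) return(0)
    p <- s / n
    if (p == 0 || p == 1) return(0)
    s * log(p) + (n - s) * log(1 - p)
  }
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_size) return(integer(0))
    cs <- cumsum(z[lo:hi])
    tot <- cs[n]
    ll_all <- bern_ll(tot, n)
    ks <- min_size:(n - min_size)
    gains <- vapply(ks, function(k) {
      bern_ll(cs[k], k) + bern_ll(tot - cs[k], n - k) - ll_all
    }, 0)
    best <- which.max(gains)
    if (gains[best] < min_gain) return(integer(0))
    split <- lo + ks[best] - 1
    c(recurse(lo, split), split, recurse(split + 1, hi))
  }
  recurse(1, length(z))
}

#' Segment a chromosome by its allele-ratio profile
#'
#' Sites are reduced to a Bernoulli indicator (allele ratio within a band
#' of 0.5, i.e. "looks diploid") and change-points found by gain-
#' thresholded binary segmentation; long het-free gaps (deserts,
#' consistent with monosomy or LOH) are split out as their own segments.
#' Each segment is then re-classified with
#' [classify_chromosome_ploidy()] restricted to its sites and bins, and
#' adjacent segments with identical state are merged.
#'
#' @param records allele-balance data.frame for one chromosome, sorted by
#'   position
#' @param window_sites retained for call compatibility; the indicator is
#'   segmented per site
#' @param min_segment_sites minimum sites per segment; fewer sites in
#'   total yields one low-confidence segment
#' @param band half-width of the "diploid-like" ratio band around 0.5
#' @param min_gain binary-segmentation log-likelihood gain threshold
#' @param desert_min_gap het-free gap (bp) treated as a desert segment
#' @param binned optional binned depth for this chromosome (enables the
#'   depth term in per-segment classification)
#' @param baseline diploid baseline depth
#' @param chrom_length chromosome length (bounds desert detection at the
#'   chromosome ends); defaults to the last site/bin position
#' @param candidates,weights see [classify_chromosome_ploidy()]
#' @return data.frame of segments: `chromosome`, `start`, `end`, `state`,
#'   `n_sites`, `mean_depth`, `low_confidence`
#' @export
segment_allele_ratio <- function(records, window_sites = 200,
                                 min_segment_sites = 100, band = 0.15,
                                 min_gain = 15, desert_min_gap = 2e6,
                                 binned = NULL, baseline = NULL,
                                 chrom_length = NULL,
                                 candidates = candidate_states(),
                                 weights = ploidy_weights(baseline)) {
  stopifnot(nrow(records) == 0 || !is.unsorted(records$position))
  chrom <- if (nrow(records) > 0) records$chromosome[1]
           else if (!is.null(binned)) binned$chromosome[1]
           else NA_character_
  if (is.null(chrom_length)) {
    chrom_length <- max(c(records$position, binned$end, 1))
  }

  segment_depth <- function(start, end) {
    if (is.null(binned)) return(NA_real_)
    sel <- binned$start <= end & binned$end >= start
    stats::median(binned$depth[sel], na.rm = TRUE)
  }
  classify_segment <- function(start, end, rec) {
    call <- classify_chromosome_ploidy(
      rec, segment_depth(start, end), baseline, candidates, weights)
    data.frame(chromosome = chrom, start = start, end = end,
               state = call$best_state, n_sites = nrow(rec),
               mean_depth = segment_depth(start, end),
               low_confidence = isTRUE(call$low_confidence) ||
                 nrow(rec) < min_segment_sites,
               stringsAsFactors = FALSE)
  }

  if (nrow(records) < min_segment_sites) {
    out <- classify_segment(1, chrom_length, records)
    out$low_confidence <- TRUE
    return(out)
  }

  pos <- records$position
  # desert boundaries: chromosome ends and interior het-free gaps
  gaps <- which(diff(pos) > desert_min_gap)
  blocks <- list()
  add <- function(lst, x) c(lst, list(x))
  if (pos[1] - 1 > desert_min_gap) {
    blocks <- add(blocks, c(1, pos[1] - 1, NA, NA))  # leading desert
  }
  idx_start <- 1
  bounds_lo <- if (pos[1] - 1 > desert_min_gap) pos[1] else 1
  for (g in gaps) {
    blocks <- add(blocks, c(bounds_lo, pos[g], idx_start, g))
    blocks <- add(blocks, c(pos[g] + 1, pos[g + 1] - 1, NA, NA))  # desert
    idx_start <- g + 1
    bounds_lo <- pos[g + 1]
  }
  trailing_desert <- chrom_length - pos[length(pos)] > desert_min_gap
  blocks <- add(blocks, c(bounds_lo,
                          if (trailing_desert) pos[length(pos)]
                          else chrom_length,
                          idx_start, length(pos)))
  if (trailing_desert) {
    blocks <- add(blocks, c(pos[length(pos)] + 1, chrom_length, NA, NA))
  }

  segs <- list()
  for (b in blocks) {
    if (is.na(b[3])) {  # desert: classify on depth/absence only
      segs <- add(segs, classify_segment(b[1], b[2], records[0, ]))
      next
    }
    rec <- records[b[3]:b[4], , drop = FALSE]
    z <- as.integer(abs(rec$ratio_alt - 0.5) <= band)
    splits <- binseg_bernoulli(z, min_size = min_segment_sites,
                               min_gain = min_gain)
    cuts <- c(0, splits, nrow(rec))
    for (j in seq_len(length(cuts) - 1)) {
      lo <- cuts[j] + 1
      hi <- cuts[j + 1]
      seg_start <- if (j == 1) b[1]
                   else floor((rec$position[lo - 1] + rec$position[lo]) / 2) + 1
      seg_end <- if (j == length(cuts) - 1) b[2]
                 else floor((rec$position[hi] + rec$position[hi + 1]) / 2)
      segs <- add(segs, classify_segment(seg_start, seg_end,
                                         rec[lo:hi, , drop = FALSE]))
    }
  }
  out <- do.call(rbind, segs)
  # merge adjacent segments with identical state
  keep <- c(TRUE, out$state[-1] != out$state[-nrow(out)])
  grp <- cumsum(keep)
  merged <- lapply(split(out, grp), function(d) {
    data.frame(chromosome = d$chromosome[1], start = min(d$start),
               end = max(d$end), state = d$state[1],
               n_sites = sum(d$n_sites),
               mean_depth = stats::median(d$mean_depth, na.rm = TRUE),
               low_confidence = all(d$low_confidence),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Detect depth anomalies (large deletions / duplications)
#'
#' Maximal runs of bins with depth below `drop_factor * median` (loss) or
#' above `(2 - drop_factor) * median` (gain), spanning at least
#' `min_length`. Because individual 50-kb bins are noisy, runs of the same
#' kind separated by at most `max_gap_bins` non-anomalous bins are merged
#' before the length gate, and a merged region is kept only if its mean
#' depth itself passes the threshold.
#'
#' @param binned binned depth data.frame (one or more chromosomes)
#' @param chrom_median optional named vector of per-chromosome median
#'   depths; computed from the bins when NULL
#' @param drop_factor loss threshold as a fraction of the median
#' @param min_length minimum anomaly span in bp
#' @param max_gap_bins longest interruption (in bins) bridged when
#'   merging runs of the same kind
#' @return data.frame `chromosome`, `start`, `end`, `mean_depth`, `kind`
#' @export
detect_depth_anomalies <- function(binned, chrom_median = NULL,
                                   drop_factor = 0.6, min_length = 1e6,
                                   max_gap_bins = 10) {
  out <- lapply(split(binned, binned$chromosome), function(tr) {
    chrom <- tr$chromosome[1]
    med <- if (!is.null(chrom_median) && chrom %in% names(chrom_median)) {
      chrom_median[[chrom]]
    } else {
      stats::median(tr$depth, na.rm = TRUE)
    }
    state <- ifelse(is.na(tr$depth), "na",
                    ifelse(tr$depth < drop_factor * med, "loss",
                           ifelse(tr$depth > (2 - drop_factor) * med,
                                  "gain", "normal")))
    rows <- list()
    for (kind in c("loss", "gain")) {
      idx <- which(state == kind)
      if (length(idx) == 0) next
      grp <- cumsum(c(1, diff(idx) > max_gap_bins + 1))
      for (g in unique(grp)) {
        bins <- idx[grp == g]
        s <- tr$start[bins[1]]
        e <- tr$end[bins[length(bins)]]
        if (e - s + 1 < min_length) next
        mean_depth <- mean(tr$depth[bins[1]:bins[length(bins)]],
                           na.rm = TRUE)
        ok <- if (kind == "loss") mean_depth < drop_factor * med
              else mean_depth > (2 - drop_factor) * med
        if (!ok) next
        rows[[length(rows) + 1]] <- data.frame(
          chromosome = chrom, start = s, end = e, mean_depth = mean_depth,
          kind = kind, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) NULL
    else {
      rows <- do.call(rbind, rows)
      rows[order(rows$start), , drop = FALSE]
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), mean_depth = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Kernel-density modes of an allele-ratio sample
#'
#' @param ratios numeric vector in (0, 1)
#' @param n_modes number of modes to report (the highest-density local
#'   maxima, returned in increasing position order); NULL returns all
#'   local maxima ordered by height
#' @param bw kernel bandwidth passed to [stats::density()]; the default
#'   0.025 sits at the granularity of count ratios (1/depth at typical
#'   30-60x sites), smoothing the discreteness without merging modes
#'   that are a copy-number step apart
#' @return numeric vector of mode positions
#' @export
allele_ratio_modes <- function(ratios, n_modes = NULL, bw = 0.025) {
  stopifnot(length(ratios) >= 10)
  d <- stats::density(ratios, bw = bw, n = 2048)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) == 0) is_max <- which.max(y)
  ord <- is_max[order(y[is_max], decreasing = TRUE)]
  if (is.null(n_modes)) return(d$x[ord])
  sort(d$x[ord[seq_len(min(n_modes, length(ord)))]])
}

#' Histogram of allele-support ratios for one chromosome
#'
#' Counts of the reference-supporting ratio in fixed-width bins, the form
#' in which per-chromosome allele balance is usually displayed.
#'
#' @param records allele-balance data.frame
#' @param binwidth histogram bin width on the ratio axis
#' @return data.frame `bin_mid`, `count`
#' @export
ratio_histogram <- function(records, binwidth = 0.02) {
  breaks <- seq(0, 1, by = binwidth)
  cut_idx <- findInterval(records$ratio_ref, breaks,
                          rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  data.frame(bin_mid = breaks[-length(breaks)] + binwidth / 2,
             count = counts)
}
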