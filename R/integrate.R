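## Feature-level aggregation and correlation of expression, methylation
## and histone-mark peak scores, plus per-chromosome dosage-expression
## comparison.

#' Expression-class bounds
#'
#' TPM is cut into five ordered classes: C0 (<= 1, not expressed or very
#' low), C1 (1, 5], C2 (5, 20], C3 (20, 100], C4 (> 100). The outer
#' bounds (1 and 100) follow the conventional "expressed" and "very high"
#' thresholds; the interior bounds are the package defaults and
#' configurable.
#'
#' @param bounds increasing numeric vector of interior cut points
#' @return the bounds vector (validated)
#' @export
expression_class_bounds <- function(bounds = c(1, 5, 20, 100)) {
  stopifnot(length(bounds) >= 1, !is.unsorted(bounds, strictly = TRUE),
            all(bounds > 0))
  bounds
}

#' Assign genes to expression classes
#'
#' @param tpm non-negative TPM values
#' @param bounds see [expression_class_bounds()]
#' @return ordered factor with levels C0 ... C{length(bounds)}; classes
#'   are right-closed: a gene exactly at a bound falls in the lower class
#' @export
assign_expression_class <- function(tpm, bounds = expression_class_bounds()) {
  if (any(is.na(tpm)) || any(tpm < 0)) stop("TPM must be non-negative")
  labels <- paste0("C", seq(0, length(bounds)))
  cut(tpm, breaks = c(-Inf, bounds, Inf), labels = labels,
      right = TRUE, ordered_result = TRUE)
}

gene_feature_ranges <- function(genes, feature, tss_window) {
  if (feature == "TSS") {
    GenomicRanges::GRanges(
      genes$chromosome,
      IRanges::IRanges(pmax(1, genes$tss - tss_window),
                       genes$tss + tss_window),
      gene = genes$gene_id)
  } else {
    # gene body: the transcribed span minus the TSS window; at most two
    # pieces per gene (left and right of the window)
    w_lo <- genes$tss - tss_window
    w_hi <- genes$tss + tss_window
    left_ok <- genes$start <= w_lo - 1
    right_ok <- w_hi + 1 <= genes$end
    pieces <- rbind(
      data.frame(chromosome = genes$chromosome[left_ok],
                 start = genes$start[left_ok],
                 end = pmin(genes$end, w_lo - 1)[left_ok],
                 gene = genes$gene_id[left_ok]),
      data.frame(chromosome = genes$chromosome[right_ok],
                 start = pmax(genes$start, w_hi + 1)[right_ok],
                 end = genes$end[right_ok],
                 gene = genes$gene_id[right_ok]))
    gr <- GenomicRanges::GRanges(
      pieces$chromosome, IRanges::IRanges(pieces$start, pieces$end))
    gr$gene <- pieces$gene
    gr
  }
}

#' Mean methylation level per gene at a feature
#'
#' Per gene, the unweighted mean level of adequately covered CpG sites in
#' the feature interval: TSS = tss +/- `tss_window`; gene body = the gene
#' span minus the TSS window. Genes with no qualifying site are NA.
#'
#' @param sites methylation data.frame
#' @param genes gene data.frame
#' @param feature "TSS" or "gene_body"
#' @param tss_window TSS half-window in bp
#' @param min_cov minimum site coverage
#' @param context sequence context used (CpG)
#' @return named numeric vector, one entry per gene
#' @export
methylation_at_feature <- function(sites, genes,
                                   feature = c("TSS", "gene_body"),
                                   tss_window = 1000, min_cov = 10,
                                   context = "CpG") {
  feature <- match.arg(feature)
  keep <- sites[sites$total_reads >= min_cov &
                  sites$context %in% context, , drop = FALSE]
  fr <- gene_feature_ranges(genes, feature, tss_window)
  out <- stats::setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  if (nrow(keep) == 0 || length(fr) == 0) return(out)
  sg <- GenomicRanges::GRanges(keep$chromosome,
                               IRanges::IRanges(keep$position, keep$position))
  hits <- GenomicRanges::findOverlaps(sg, fr)
  if (length(hits) == 0) return(out)
  vals <- tapply(keep$level[S4Vectors::queryHits(hits)],
                 fr$gene[S4Vectors::subjectHits(hits)], mean)
  out[names(vals)] <- vals
  out
}

#' Maximum peak score near each TSS
#'
#' Per gene, the maximum score among peaks intersecting
#' tss +/- `window`; 0 when no peak is near.
#'
#' @param peaks peak data.frame
#' @param genes gene data.frame
#' @param window TSS half-window in bp
#' @param value_col score column used ("signal_value" or "peak_score")
#' @return named numeric vector, one entry per gene
#' @export
peak_score_at_gene <- function(peaks, genes, window = 2000,
                               value_col = c("signal_value", "peak_score")) {
  value_col <- match.arg(value_col)
  out <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (nrow(peaks) == 0) return(out)
  tss <- GenomicRanges::GRanges(
    genes$chromosome,
    IRanges::IRanges(pmax(1, genes$tss - window), genes$tss + window))
  hits <- GenomicRanges::findOverlaps(tss, peaks_gr(peaks))
  if (length(hits) == 0) return(out)
  mx <- tapply(peaks[[value_col]][S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), max)
  out[as.integer(names(mx))] <- mx
  out
}

#' Build the per-gene feature table
#'
#' One row per gene: TPM and expression class, TSS and gene-body
#' methylation from each assay, and the peak score of each supplied mark
#' near the TSS.
#'
#' @param genes gene data.frame with TPM
#' @param rrbs,wgbs methylation tables (either may be NULL)
#' @param peak_sets named list of peak data.frames (e.g. H3K4me3 = ...)
#' @param tss_window TSS half-window for methylation (bp)
#' @param score_window TSS half-window for peak scores (bp)
#' @param min_cov minimum methylation site coverage
#' @param class_bounds see [expression_class_bounds()]
#' @return data.frame with columns `gene_id`, `chromosome`, `tpm`,
#'   `expression_class`, `RRBS_TSS`, `RRBS_GB`, `WGBS_TSS`, `WGBS_GB`
#'   (when assays given) and one column per mark
#' @export
gene_feature_table <- function(genes, rrbs = NULL, wgbs = NULL,
                               peak_sets = list(), tss_window = 1000,
                               score_window = 2000, min_cov = 10,
                               class_bounds = expression_class_bounds()) {
  out <- data.frame(gene_id = genes$gene_id,
                    chromosome = genes$chromosome,
                    tpm = genes$tpm,
                    expression_class = assign_expression_class(genes$tpm,
                                                               class_bounds),
                    stringsAsFactors = FALSE)
  if (!is.null(rrbs)) {
    out$RRBS_TSS <- unname(methylation_at_feature(rrbs, genes, "TSS",
                                                  tss_window, min_cov))
    out$RRBS_GB <- unname(methylation_at_feature(rrbs, genes, "gene_body",
                                                 tss_window, min_cov))
  }
  if (!is.null(wgbs)) {
    out$WGBS_TSS <- unname(methylation_at_feature(wgbs, genes, "TSS",
                                                  tss_window, min_cov))
    out$WGBS_GB <- unname(methylation_at_feature(wgbs, genes, "gene_body",
                                                 tss_window, min_cov))
  }
  for (mark in names(peak_sets)) {
    out[[mark]] <- unname(peak_score_at_gene(peak_sets[[mark]], genes,
                                             score_window))
  }
  out
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param table data.frame (e.g. from [gene_feature_table()])
#' @param columns columns to correlate; defaults to all numeric columns
#' @param min_complete minimum complete pairs required per entry
#' @return symmetric correlation matrix with unit diagonal; entries with
#'   too few complete pairs or a constant column are NA
#' @export
correlation_matrix <- function(table, columns = NULL, min_complete = 3) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  x <- as.matrix(table[, columns, drop = FALSE])
  cc <- crossprod(!is.na(x))  # complete-pair counts
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  r[cc < min_complete] <- NA_real_
  diag(r) <- 1
  r
}

#' Per-chromosome expression summary and dosage shift test
#'
#' Summarizes TPM per chromosome among genes above an expression floor
#' (removing the unexpressed mass that would swamp the quartiles), and —
#' when aneuploid and diploid chromosome sets are declared — compares the
#' two gene populations with a Wilcoxon rank-sum test and a median-ratio
#' effect size.
#'
#' @param genes gene data.frame with TPM
#' @param min_tpm expression floor (genes with TPM > min_tpm are used)
#' @param aneuploid,diploid optional character vectors of chromosome
#'   names for the shift test
#' @param min_genes chromosomes with fewer qualifying genes are flagged
#'   and excluded from the test
#' @return list with `summary` (per-chromosome n, median, q1, q3,
#'   flagged) and, when both sets are given, `test` (median_ratio,
#'   p_value, n_aneuploid, n_diploid)
#' @export
chromosome_expression_summary <- function(genes, min_tpm = 2,
                                          aneuploid = NULL, diploid = NULL,
                                          min_genes = 5) {
  expr <- genes[!is.na(genes$tpm) & genes$tpm > min_tpm, , drop = FALSE]
  chroms <- sort(unique(genes$chromosome))
  summary <- do.call(rbind, lapply(chroms, function(chrom) {
    tpm <- expr$tpm[expr$chromosome == chrom]
    data.frame(chromosome = chrom, n = length(tpm),
               median = if (length(tpm)) stats::median(tpm) else NA_real_,
               q1 = if (length(tpm)) unname(stats::quantile(tpm, 0.25))
                    else NA_real_,
               q3 = if (length(tpm)) unname(stats::quantile(tpm, 0.75))
                    else NA_real_,
               flagged = length(tpm) < min_genes,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  out <- list(summary = summary)
  if (!is.null(aneuploid) && !is.null(diploid)) {
    usable <- summary$chromosome[!summary$flagged]
    an <- expr$tpm[expr$chromosome %in% intersect(aneuploid, usable)]
    di <- expr$tpm[expr$chromosome %in% intersect(diploid, usable)]
    if (length(an) == 0 || length(di) == 0) {
      stop("no qualifying genes in one of the chromosome sets")
    }
    wt <- stats::wilcox.test(an, di)
    out$test <- list(median_ratio = stats::median(an) / stats::median(di),
                     p_value = wt$p.value,
                     n_aneuploid = length(an), n_diploid = length(di))
  }
  out
}
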