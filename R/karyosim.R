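## Truth-labelled synthetic karyotype/epigenome generator. Every downstream
## stage (ploidy inference, enhancer calling, RRBS/WGBS complementarity,
## integrative correlation) is validated against the truth labels this
## module emits.

#' Label for a copy-number / allele configuration
#'
#' "3:AAB" means three copies, one carrying the alternate allele;
#' "4:AABB" a balanced tetraploid; "1" a monosomy; "2:AA" copy-neutral
#' loss of heterozygosity.
#'
#' @param total_copies copy number c (>= 0)
#' @param alt_copies number of copies carrying the alternate allele at a
#'   het site (k); ignored for c <= 1
#' @return character label
#' @export
state_label <- function(total_copies, alt_copies = NA) {
  if (total_copies <= 1) return(as.character(total_copies))
  if (is.na(alt_copies)) alt_copies <- 1
  paste0(total_copies, ":",
         strrep("A", total_copies - alt_copies), strrep("B", alt_copies))
}

#' Define a synthetic karyotype
#'
#' @param layout [genome_layout()] of the simulated genome
#' @param segments data.frame with columns `chromosome`, `start`, `end`,
#'   `total_copies`, `alt_copies`; the segments must tile each chromosome
#'   of the layout without gaps or overlap. `alt_copies` is the number of
#'   copies carrying the alternate allele at heterozygous sites (0 or
#'   `total_copies` encodes LOH: no het sites are produced).
#' @param baseline_depth mean sequencing depth at copy number 2
#' @param het_rate heterozygous sites per bp on het-capable segments
#' @param overdispersion beta-binomial intra-class correlation for allele
#'   counts (mapping-bias proxy)
#' @param depth_dispersion negative-binomial size parameter for per-bin
#'   depth (larger = closer to Poisson)
#' @return list of class `karyotype_spec`
#' @export
karyotype_spec <- function(layout, segments, baseline_depth = 30,
                           het_rate = 2e-5, overdispersion = 0.01,
                           depth_dispersion = 100) {
  stopifnot(baseline_depth > 0, het_rate > 0, overdispersion >= 0)
  need <- c("chromosome", "start", "end", "total_copies", "alt_copies")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  segments <- segments[order(segments$chromosome, segments$start), ,
                       drop = FALSE]
  for (chrom in layout$chromosome) {
    seg <- segments[segments$chromosome == chrom, , drop = FALSE]
    if (nrow(seg) == 0) stop("no segments for chromosome ", chrom)
    len <- chrom_length(layout, chrom)
    if (seg$start[1] != 1 || seg$end[nrow(seg)] != len ||
        (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1))) {
      stop("segments must tile chromosome ", chrom, " without gaps/overlap")
    }
  }
  bad <- segments$alt_copies > segments$total_copies | segments$alt_copies < 0
  if (any(bad, na.rm = TRUE)) stop("alt_copies must lie in [0, total_copies]")
  segments$label <- mapply(state_label, segments$total_copies,
                           segments$alt_copies)
  structure(list(layout = layout, segments = segments,
                 baseline_depth = baseline_depth, het_rate = het_rate,
                 overdispersion = overdispersion,
                 depth_dispersion = depth_dispersion),
            class = "karyotype_spec")
}

#' Preset karyotypes mimicking immortalized cell lines
#'
#' The "ipecj2" preset is a mostly diploid desk-scale genome with the
#' abnormality patterns seen in aneuploid cultured lines: one whole
#' trisomic chromosome, one chromosome whose distal 40% is 4:AAAB (allele
#' modes 0.25/0.75 after a diploid proximal part), one chromosome with a
#' monosomic (het-desert) proximal half and 4:AAAB distal half, and one
#' diploid chromosome carrying an 8-Mb hemizygous deletion at 9-17 Mb.
#' The "sl29" preset adds a balanced tetraploid (4:AABB) chromosome, whose
#' allele modes sit at 0.5 and which is separable from diploidy only by
#' depth.
#'
#' @param preset "ipecj2" or "sl29"
#' @param baseline_depth mean depth at copy number 2
#' @param het_rate het sites per bp
#' @param ... passed on to [karyotype_spec()]
#' @return a `karyotype_spec`
#' @export
karyotype_preset <- function(preset = c("ipecj2", "sl29"),
                             baseline_depth = 30, het_rate = 2e-5, ...) {
  preset <- match.arg(preset)
  seg <- function(chrom, start, end, c, k) {
    data.frame(chromosome = chrom, start = start, end = end,
               total_copies = c, alt_copies = k, stringsAsFactors = FALSE)
  }
  chroms <- c(chr1 = 120e6, chr2 = 100e6, chr3 = 80e6, chr4 = 60e6,
              chr5 = 60e6)
  segments <- rbind(
    seg("chr1", 1, 120e6, 2, 1),                    # diploid reference
    seg("chr2", 1, 60e6, 2, 1),                     # chr-2 pattern:
    seg("chr2", 60e6 + 1, 100e6, 4, 1),             #   distal 4:AAAB
    seg("chr3", 1, 40e6, 1, 0),                     # chr-8 pattern:
    seg("chr3", 40e6 + 1, 80e6, 4, 1),              #   desert + 4:AAAB
    seg("chr4", 1, 9e6, 2, 1),                      # chr-16 pattern:
    seg("chr4", 9e6 + 1, 17e6, 1, 0),               #   8-Mb deletion
    seg("chr4", 17e6 + 1, 60e6, 2, 1),
    seg("chr5", 1, 60e6, 3, 1)                      # whole-chr trisomy
  )
  if (preset == "sl29") {
    chroms <- c(chroms, chr6 = 50e6)
    segments <- rbind(segments, seg("chr6", 1, 50e6, 4, 2))  # tetraploid
  }
  layout <- genome_layout(names(chroms), unname(chroms))
  karyotype_spec(layout, segments, baseline_depth = baseline_depth,
                 het_rate = het_rate, ...)
}

#' Single-segment karyotype helper
#'
#' Convenience wrapper for simulating one chromosome held entirely in one
#' copy-number configuration.
#'
#' @param total_copies,alt_copies the configuration
#' @param length chromosome length in bp
#' @param chromosome chromosome name
#' @param ... passed to [karyotype_spec()]
#' @return a `karyotype_spec`
#' @export
uniform_karyotype <- function(total_copies, alt_copies, length = 100e6,
                              chromosome = "chr1", ...) {
  layout <- genome_layout(chromosome, length)
  segments <- data.frame(chromosome = chromosome, start = 1, end = length,
                         total_copies = total_copies,
                         alt_copies = alt_copies, stringsAsFactors = FALSE)
  karyotype_spec(layout, segments, ...)
}

#' Simulate WGS evidence from a karyotype
#'
#' Per-bin depth is negative-binomial with mean `baseline_depth * c/2`
#' (copy number scales coverage); heterozygous sites are placed as a
#' Poisson process on segments with c >= 2 and 0 < k < c, and the
#' alt-supporting read count at each site is beta-binomial with mean
#' `k/c` of the site depth. Monosomic and LOH segments yield no het sites.
#'
#' @param spec a [karyotype_spec()]
#' @param seed integer seed (required; simulation must be reproducible)
#' @param bin_size depth bin width in bp
#' @return list with elements `depth` (binned track data.frame), `snvs`
#'   (allele-balance data.frame with `chromosome`, `position`,
#'   `ref_reads`, `alt_reads`, `ratio_alt`, `ratio_ref`) and `truth`
#'   (per-segment and per-chromosome labels plus the generating
#'   parameters)
#' @export
simulate_wgs <- function(spec, seed, bin_size = 50000) {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  depth_list <- list()
  snv_list <- list()
  for (chrom in spec$layout$chromosome) {
    len <- chrom_length(spec$layout, chrom)
    seg <- spec$segments[spec$segments$chromosome == chrom, , drop = FALSE]

    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    # length-weighted mean copy number per bin
    bins <- IRanges::IRanges(starts, ends)
    segr <- IRanges::IRanges(seg$start, seg$end)
    hits <- IRanges::findOverlaps(bins, segr)
    ov <- IRanges::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(hits)], segr[S4Vectors::subjectHits(hits)]))
    cw <- tapply(ov * seg$total_copies[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), sum)
    wsum <- tapply(ov, S4Vectors::queryHits(hits), sum)
    copy <- rep(NA_real_, length(bins))
    copy[as.integer(names(cw))] <- cw / wsum
    mu <- spec$baseline_depth * copy / 2
    depth <- ifelse(mu > 0,
                    stats::rnbinom(length(mu), mu = pmax(mu, 1e-9),
                                   size = spec$depth_dispersion),
                    0)
    depth_list[[chrom]] <- data.frame(
      chromosome = chrom, start = starts, end = ends, depth = depth,
      stringsAsFactors = FALSE)

    for (i in seq_len(nrow(seg))) {
      c_tot <- seg$total_copies[i]
      k_alt <- seg$alt_copies[i]
      if (c_tot < 2 || k_alt <= 0 || k_alt >= c_tot) next
      span <- seg$end[i] - seg$start[i] + 1
      n_sites <- stats::rpois(1, span * spec$het_rate)
      if (n_sites == 0) next
      pos <- sort(sample.int(span, n_sites, replace = FALSE)) +
        seg$start[i] - 1
      n <- stats::rpois(n_sites, spec$baseline_depth * c_tot / 2)
      # the reference allele lies on either haplotype class with equal
      # probability, so the alt fraction is k/c or 1-k/c per site: this
      # is what makes both modes appear in one chromosome's histogram
      p_alt <- sample(c(k_alt / c_tot, 1 - k_alt / c_tot), n_sites,
                      replace = TRUE)
      alt <- rbetabinom(n_sites, n, p_alt, spec$overdispersion)
      keep <- alt > 0 & alt < n
      snv_list[[paste0(chrom, ".", i)]] <- data.frame(
        chromosome = chrom, position = pos[keep],
        ref_reads = (n - alt)[keep], alt_reads = alt[keep],
        stringsAsFactors = FALSE)
    }
  }
  depth <- do.call(rbind, depth_list)
  snvs <- if (length(snv_list) > 0) do.call(rbind, snv_list)
          else empty_allele_balance()[, 1:4]
  if (nrow(snvs) > 0) {
    snvs$ratio_alt <- snvs$alt_reads / (snvs$ref_reads + snvs$alt_reads)
    snvs$ratio_ref <- 1 - snvs$ratio_alt
    snvs <- snvs[order(snvs$chromosome, snvs$position), , drop = FALSE]
  }
  rownames(depth) <- rownames(snvs) <- NULL

  truth <- sim_truth(spec)
  list(depth = depth, snvs = snvs, truth = truth)
}

## Dominant (span-weighted) state per chromosome plus segment labels.
sim_truth <- function(spec) {
  seg <- spec$segments
  dominant <- vapply(spec$layout$chromosome, function(chrom) {
    s <- seg[seg$chromosome == chrom, , drop = FALSE]
    w <- tapply(s$end - s$start + 1, s$label, sum)
    names(w)[which.max(w)]
  }, "")
  list(
    chromosome_state = data.frame(chromosome = spec$layout$chromosome,
                                  state = unname(dominant),
                                  stringsAsFactors = FALSE),
    segments = seg,
    baseline_depth = spec$baseline_depth,
    het_rate = spec$het_rate
  )
}

#' Simulate a dosage-scaled expression table
#'
#' Baseline TPM is log-normal; each gene's expressed abundance is scaled by
#' `(c/2)^dosage_exponent` where c is the copy number at its TSS, and the
#' table is renormalized to sum to 1e6 (true TPM semantics), so dosage
#' effects appear as relative shifts between chromosomes.
#'
#' @param spec a [karyotype_spec()]
#' @param n_genes number of genes
#' @param dosage_exponent 0 = no dosage effect, 1 = proportional dosage
#' @param seed integer seed
#' @param meanlog,sdlog parameters of the baseline log-normal
#' @param silent_fraction fraction of genes with no expression at all;
#'   the default mirrors the roughly one-third-expressed proportion of
#'   real transcriptomes, and with the default gene count it spreads the
#'   renormalized table across all expression classes
#' @return list with `genes` (gene_id, chromosome, strand, start, end,
#'   tss, tes, tpm) and `truth` (per-gene copy number and dosage factor,
#'   pre-normalization baseline)
#' @export
simulate_expression <- function(spec, n_genes = 20000, dosage_exponent = 1,
                                seed, meanlog = 0, sdlog = 1.5,
                                silent_fraction = 0.66) {
  stopifnot(inherits(spec, "karyotype_spec"), n_genes >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  layout <- spec$layout
  chrom <- sample(layout$chromosome, n_genes, replace = TRUE,
                  prob = layout$length)
  len <- chrom_length(layout, chrom)
  gene_len <- pmin(round(stats::rlnorm(n_genes, log(2e4), 0.7)), 2e5)
  start <- floor(stats::runif(n_genes, 1, len - gene_len))
  end <- start + gene_len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- ifelse(strand == "+", start, end)

  copy <- copy_number_at(spec, chrom, tss)
  baseline <- stats::rlnorm(n_genes, meanlog, sdlog)
  baseline[stats::runif(n_genes) < silent_fraction] <- 0
  scaled <- baseline * (copy / 2)^dosage_exponent
  tpm <- scaled / sum(scaled) * 1e6
  genes <- data.frame(
    gene_id = sprintf("SIMG%05d", seq_len(n_genes)),
    chromosome = chrom, strand = strand, start = start, end = end,
    tss = tss, tes = ifelse(strand == "+", end, start), tpm = tpm,
    stringsAsFactors = FALSE)
  o <- order(genes$chromosome, genes$start)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  truth <- data.frame(gene_id = genes$gene_id,
                      copy_number = copy[o],
                      dosage_factor = (copy[o] / 2)^dosage_exponent,
                      baseline_tpm = baseline[o],
                      stringsAsFactors = FALSE)
  list(genes = genes, truth = truth)
}

copy_number_at <- function(spec, chrom, pos) {
  seg <- spec$segments
  out <- rep(NA_real_, length(chrom))
  for (i in seq_len(nrow(seg))) {
    hit <- chrom == seg$chromosome[i] & pos >= seg$start[i] &
      pos <= seg$end[i]
    out[hit] <- seg$total_copies[i]
  }
  out
}

#' Default parameters for the epigenome simulator
#'
#' @param gene_body_meth_slope sign/size of the gene-body methylation trend
#'   with log expression: positive ("pig mode", gene-body methylation rises
#'   slightly with expression) or negative ("chicken mode")
#' @param rrbs_exclusive_fraction fraction of promoter CpGs emitted with
#'   RRBS coverage >= 10 but WGBS coverage < 10 (the truth RRBS-exclusive
#'   set)
#' @param rrbs_promoter_cov,wgbs_cov mean coverages of the two assays
#' @param n_enhancers distal H3K27ac-only peaks per genome
#' @param tss_cpg_n CpGs simulated per promoter (TSS +/- 1 kb)
#' @param gb_cpg_n CpGs simulated per gene body
#' @return named list of parameters
#' @export
epigenome_params <- function(gene_body_meth_slope = 0.3,
                             rrbs_exclusive_fraction = 0.1,
                             rrbs_promoter_cov = 70, wgbs_cov = 30,
                             n_enhancers = 300, tss_cpg_n = 8,
                             gb_cpg_n = 6) {
  list(gene_body_meth_slope = gene_body_meth_slope,
       rrbs_exclusive_fraction = rrbs_exclusive_fraction,
       rrbs_promoter_cov = rrbs_promoter_cov, wgbs_cov = wgbs_cov,
       n_enhancers = n_enhancers, tss_cpg_n = tss_cpg_n,
       gb_cpg_n = gb_cpg_n)
}

#' Simulate histone-mark peaks and methylation tables from expression
#'
#' Encodes the regulatory relationships the integrative analysis is meant
#' to recover: active promoters (high TPM) get H3K4me3 and H3K27ac peaks
#' whose probability and signal rise with log TPM; silent genes get an
#' H3K27me3 domain instead; distal H3K27ac-only peaks placed >= 2 kb from
#' every TSS are the truth enhancers; TSS CpG methylation decreases with
#' log TPM (the canonical inverse promoter relationship) while the
#' gene-body trend has a configurable sign; and a configurable fraction of
#' promoter CpGs is emitted RRBS-covered but WGBS-undercovered (the truth
#' RRBS-exclusive set).
#'
#' @param genes gene data.frame with TPM (from [simulate_expression()])
#' @param seed integer seed
#' @param params see [epigenome_params()]
#' @param layout optional [genome_layout()] bounding enhancer placement;
#'   inferred from gene extents when absent
#' @return list with `peaks` (named list of peak data.frames for H3K4me3,
#'   H3K27ac, H3K4me1, H3K27me3), `rrbs`, `wgbs` (methylation tables) and
#'   `truth` (enhancer intervals, RRBS-exclusive site positions, per-gene
#'   regulatory state)
#' @export
simulate_epigenome <- function(genes, seed, params = epigenome_params(),
                               layout = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(all(!is.na(genes$tpm)))
  set.seed(seed)
  n <- nrow(genes)
  logt <- log10(genes$tpm + 0.1)

  p_silent <- stats::plogis(-1.5 - 2.5 * logt)
  silent <- stats::runif(n) < p_silent
  p_k4 <- stats::plogis(1.0 + 1.5 * logt)
  has_k4me3 <- !silent & stats::runif(n) < p_k4
  # promoter H3K27ac only on H3K4me3-marked promoters (active promoters
  # carry both marks; that is what makes the distance rule identify the
  # distal peaks exactly)
  has_k27ac <- has_k4me3 & stats::runif(n) < stats::plogis(0.5 + 1.5 * logt)
  has_k27me3 <- silent | stats::runif(n) < stats::plogis(-2 - 1.5 * logt)
  has_k4me1 <- stats::runif(n) < 0.4

  promoter_peak <- function(idx, jitter = 150, width_mean = 1200,
                            sig_base = 0.8, sig_slope = 0.9) {
    m <- length(idx)
    centre <- genes$tss[idx] + round(stats::rnorm(m, 0, jitter))
    w <- pmax(300, round(stats::rlnorm(m, log(width_mean), 0.3)))
    sig <- stats::rlnorm(m, sig_base + sig_slope * logt[idx], 0.35)
    data.frame(chromosome = genes$chromosome[idx],
               start = pmax(1, centre - w %/% 2),
               end = pmax(1, centre - w %/% 2) + w,
               name = paste0("pk_", idx),
               peak_score = round(40 + 60 * pmin(sig, 20)),
               strand = ".", signal_value = sig,
               pvalue = -1, qvalue = -1, summit_offset = w %/% 2,
               stringsAsFactors = FALSE)
  }

  k4me3 <- promoter_peak(which(has_k4me3))
  k27ac_prom <- promoter_peak(which(has_k27ac), sig_base = 0.5)

  # distal truth enhancers: H3K27ac-only, >= 2 kb away from every TSS
  if (is.null(layout)) {
    agg <- tapply(genes$end, genes$chromosome, max)
    layout <- genome_layout(names(agg), as.numeric(agg) + 1e6)
  }
  n_enh <- params$n_enhancers
  enh_chrom <- sample(layout$chromosome, n_enh * 3, replace = TRUE,
                      prob = layout$length)
  enh_pos <- floor(stats::runif(n_enh * 3, 2e4,
                                chrom_length(layout, enh_chrom) - 2e4))
  tss_gr <- GenomicRanges::GRanges(
    genes$chromosome,
    IRanges::IRanges(pmax(1, genes$tss - 4000), genes$tss + 4000))
  cand <- GenomicRanges::GRanges(enh_chrom,
                                 IRanges::IRanges(enh_pos - 500, enh_pos + 500))
  clear <- !IRanges::overlapsAny(cand, tss_gr)
  keep <- which(clear)[seq_len(min(n_enh, sum(clear)))]
  enhancers <- data.frame(
    chromosome = enh_chrom[keep],
    start = enh_pos[keep] - 500, end = enh_pos[keep] + 500,
    name = paste0("enh_", seq_along(keep)),
    peak_score = round(stats::runif(length(keep), 50, 300)),
    strand = ".",
    signal_value = stats::rlnorm(length(keep), 1.2, 0.4),
    pvalue = -1, qvalue = -1, summit_offset = 500,
    stringsAsFactors = FALSE)

  k27ac <- rbind(k27ac_prom, enhancers)
  k27me3 <- local({
    idx <- which(has_k27me3)
    data.frame(chromosome = genes$chromosome[idx],
               start = pmax(1, genes$start[idx] - 1000),
               end = genes$end[idx] + 1000,
               name = paste0("dom_", idx),
               peak_score = round(stats::runif(length(idx), 30, 120)),
               strand = ".",
               signal_value = stats::rlnorm(length(idx),
                                            0.8 - 0.3 * logt[idx], 0.4),
               pvalue = -1, qvalue = -1, summit_offset = NA_real_,
               stringsAsFactors = FALSE)
  })
  k4me1 <- local({
    idx <- which(has_k4me1)
    m <- length(idx)
    offset <- sample(c(-1, 1), m, TRUE) * round(stats::runif(m, 1500, 6000))
    centre <- genes$tss[idx] + offset
    data.frame(chromosome = genes$chromosome[idx],
               start = pmax(1, centre - 700), end = pmax(1, centre - 700) + 1400,
               name = paste0("k4me1_", idx),
               peak_score = round(stats::runif(m, 30, 150)),
               strand = ".",
               signal_value = stats::rlnorm(m, 0.9, 0.35),
               pvalue = -1, qvalue = -1, summit_offset = 700,
               stringsAsFactors = FALSE)
  })
  sort_peaks <- function(df) {
    df <- df[order(df$chromosome, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  peaks <- list(H3K4me3 = peak_set(sort_peaks(k4me3), mark = "H3K4me3"),
                H3K27ac = peak_set(sort_peaks(k27ac), mark = "H3K27ac"),
                H3K4me1 = peak_set(sort_peaks(k4me1), mark = "H3K4me1"),
                H3K27me3 = peak_set(sort_peaks(k27me3), mark = "H3K27me3"))

  ## methylation: promoter CpGs anticorrelated with expression,
  ## gene-body trend sign configurable
  meth <- simulate_methylation(genes, logt, params)

  truth <- list(
    enhancers = enhancers[order(enhancers$chromosome, enhancers$start),
                          c("chromosome", "start", "end")],
    rrbs_exclusive = meth$rrbs_exclusive,
    gene_state = data.frame(gene_id = genes$gene_id, silent = silent,
                            has_k4me3 = has_k4me3, has_k27ac = has_k27ac,
                            has_k27me3 = has_k27me3,
                            stringsAsFactors = FALSE))
  rownames(truth$enhancers) <- NULL
  list(peaks = peaks, rrbs = meth$rrbs, wgbs = meth$wgbs, truth = truth)
}

simulate_methylation <- function(genes, logt, params) {
  n <- nrow(genes)
  site_rows <- function(chrom, pos, level, cov) {
    keep <- cov > 0
    meth <- stats::rbinom(sum(keep), cov[keep], level[keep])
    data.frame(chromosome = chrom[keep], position = pos[keep], strand = "+",
               context = "CpG", methylated_reads = meth,
               total_reads = cov[keep], level = meth / cov[keep],
               stringsAsFactors = FALSE)
  }
  mu_beta <- function(mu, phi = 30) {
    mu <- pmin(pmax(mu, 0.02), 0.98)
    stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  }

  # promoter CpGs
  m <- params$tss_cpg_n
  idx <- rep(seq_len(n), each = m)
  pos <- pmax(1, genes$tss[idx] + round(stats::runif(n * m, -1000, 1000)))
  mu_tss <- stats::plogis(1.4 - 1.5 * logt[idx])
  lvl <- mu_beta(mu_tss)
  rrbs_cov <- stats::rpois(n * m, params$rrbs_promoter_cov)
  excl <- stats::runif(n * m) < params$rrbs_exclusive_fraction
  wgbs_cov <- stats::rpois(n * m, params$wgbs_cov)
  wgbs_cov[excl] <- pmin(stats::rpois(sum(excl), 3), 9)
  rrbs_excl_truth <- excl & rrbs_cov >= 10

  rrbs_tss <- site_rows(genes$chromosome[idx], pos, lvl, rrbs_cov)
  wgbs_tss <- site_rows(genes$chromosome[idx], pos, lvl, wgbs_cov)
  rrbs_exclusive <- data.frame(
    chromosome = genes$chromosome[idx][rrbs_excl_truth],
    position = pos[rrbs_excl_truth], stringsAsFactors = FALSE)

  # gene-body CpGs (WGBS everywhere; RRBS only a sparse subset)
  g <- params$gb_cpg_n
  gidx <- rep(seq_len(n), each = g)
  gpos <- pmax(1, round(stats::runif(n * g, genes$start[gidx],
                                     genes$end[gidx])))
  # keep gene-body sites clear of the promoter window so promoter and
  # gene-body CpGs never share a position
  near_tss <- abs(gpos - genes$tss[gidx]) <= 1200
  gpos[near_tss] <- gpos[near_tss] + 2500
  mu_gb <- stats::plogis(0.4 + params$gene_body_meth_slope * logt[gidx])
  glvl <- mu_beta(mu_gb)
  gb_wgbs_cov <- stats::rpois(n * g, params$wgbs_cov)
  on_rrbs <- stats::runif(n * g) < 0.2
  gb_rrbs_cov <- ifelse(on_rrbs,
                        stats::rpois(n * g, params$rrbs_promoter_cov), 0)
  wgbs_gb <- site_rows(genes$chromosome[gidx], gpos, glvl, gb_wgbs_cov)
  rrbs_gb <- site_rows(genes$chromosome[gidx], gpos, glvl, gb_rrbs_cov)

  # sparse non-CpG background (bisulfite data is mostly unmethylated there)
  bg <- max(200, n)
  bchrom <- sample(genes$chromosome, bg, replace = TRUE)
  bpos <- round(stats::runif(bg, 1, max(genes$end)))
  bctx <- sample(c("CHG", "CHH"), bg, replace = TRUE)
  bcov <- stats::rpois(bg, params$wgbs_cov)
  bkeep <- bcov > 0
  bmeth <- stats::rbinom(sum(bkeep), bcov[bkeep], 0.02)
  background <- data.frame(chromosome = bchrom[bkeep], position = bpos[bkeep],
                           strand = "+", context = bctx[bkeep],
                           methylated_reads = bmeth, total_reads = bcov[bkeep],
                           level = bmeth / bcov[bkeep],
                           stringsAsFactors = FALSE)

  tidy <- function(df) {
    df <- df[order(df$chromosome, df$position), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(rrbs = tidy(rbind(rrbs_tss, rrbs_gb)),
       wgbs = tidy(rbind(wgbs_tss, wgbs_gb, background)),
       rrbs_exclusive = tidy(rrbs_exclusive))
}
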