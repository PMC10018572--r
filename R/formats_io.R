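## Readers/writers for the external formats consumed and produced by the
## pipeline. All coordinates are held 1-based closed internally (the
## IRanges convention); BED-family files are shifted on read and back on
## write, so a read/write round trip is the identity.

#' Read heterozygous allele depths from a VCF
#'
#' Extracts per-site allele-supporting read counts for heterozygous,
#' biallelic SNVs from a VCF with GT and AD genotype fields. The
#' allele-support ratio at such sites is the primary evidence for ploidy
#' inference: its modes sit at k/c and 1 - k/c for a chromosome with c
#' copies of which k carry the alternate allele.
#'
#' @param path VCF file (plain text or bgzipped)
#' @param min_site_depth minimum ref+alt depth for a site to be kept
#' @param sample sample name; defaults to the first sample in the file
#' @return data.frame with columns `chromosome`, `position`, `ref_reads`,
#'   `alt_reads`, `ratio_alt`, `ratio_ref`, ordered by chromosome and
#'   position
#' @export
read_vcf_allele_depths <- function(path, min_site_depth = 10, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-variant files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) {
    return(empty_allele_balance())
  }
  fmt <- vcf@gt[, 1]
  if (!all(grepl("AD", fmt))) {
    bad <- which(!grepl("AD", fmt))[1]
    stop("no AD (allele depth) field at site ",
         fix[bad, "CHROM"], ":", fix[bad, "POS"])
  }
  samples <- colnames(vcf@gt)[-1]
  col <- if (is.null(sample)) samples[1] else sample
  if (!col %in% samples) stop("sample not present in VCF: ", col)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, col]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, col]

  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "" &
    !is.na(fix[, "ALT"])
  gt_norm <- gsub("\\|", "/", gt)
  malformed <- !is.na(gt_norm) & !gt_norm %in% c("0/0", "0/1", "1/0", "1/1")
  if (any(malformed)) {
    warning(sum(malformed), " site(s) with unparseable genotype skipped")
  }
  het <- !is.na(gt_norm) & gt_norm %in% c("0/1", "1/0")

  keep <- which(biallelic & het)
  if (length(keep) == 0) {
    return(empty_allele_balance())
  }
  parts <- strsplit(ad[keep], ",", fixed = TRUE)
  ok <- lengths(parts) >= 2
  ref_reads <- rep(NA_real_, length(keep))
  alt_reads <- rep(NA_real_, length(keep))
  ref_reads[ok] <- as.numeric(vapply(parts[ok], `[`, "", 1))
  alt_reads[ok] <- as.numeric(vapply(parts[ok], `[`, "", 2))
  dp <- ref_reads + alt_reads
  pass <- ok & !is.na(dp) & dp >= min_site_depth & ref_reads > 0 & alt_reads > 0
  keep <- keep[pass]
  out <- data.frame(
    chromosome = fix[keep, "CHROM"],
    position = as.numeric(fix[keep, "POS"]),
    ref_reads = ref_reads[pass],
    alt_reads = alt_reads[pass],
    stringsAsFactors = FALSE
  )
  out$ratio_alt <- out$alt_reads / (out$ref_reads + out$alt_reads)
  out$ratio_ref <- 1 - out$ratio_alt
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_allele_balance <- function() {
  data.frame(chromosome = character(), position = numeric(),
             ref_reads = numeric(), alt_reads = numeric(),
             ratio_alt = numeric(), ratio_ref = numeric(),
             stringsAsFactors = FALSE)
}

peak_columns <- c("chromosome", "start", "end", "name", "peak_score",
                  "strand", "signal_value", "pvalue", "qvalue",
                  "summit_offset")

#' Read a peak file
#'
#' Reads ENCODE narrowPeak (BED6+4), broadPeak (BED6+3) or bare BED3 into a
#' sorted peak table. `signal_value` is the enrichment statistic (column 7
#' of narrowPeak/broadPeak); `peak_score` is the integer score column 5.
#'
#' @param path peak file
#' @param dialect one of "narrowPeak", "broadPeak", "bed3"
#' @param mark optional mark label (e.g. "H3K27ac") attached to the result
#' @param replicate optional replicate label
#' @return data.frame of peaks sorted by (chromosome, start), 1-based
#'   closed coordinates, class `peak_set`
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed3"),
                       mark = NA_character_, replicate = NA_character_) {
  dialect <- match.arg(dialect)
  ncol_expect <- switch(dialect, narrowPeak = 10, broadPeak = 9, bed3 = 3)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0 || all(lines == "")) {
    return(peak_set(empty_peaks(), mark = mark, replicate = replicate))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad) > 0) {
    stop("expected ", ncol_expect, " columns for ", dialect,
         " but found ", lengths(fields)[bad[1]], " at line ", bad[1])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    chromosome = m[, 1],
    start = as.numeric(m[, 2]) + 1,  # BED half-open -> 1-based closed
    end = as.numeric(m[, 3]),
    stringsAsFactors = FALSE
  )
  if (dialect == "bed3") {
    df$name <- NA_character_
    df$peak_score <- NA_real_
    df$strand <- "."
    df$signal_value <- NA_real_
    df$pvalue <- NA_real_
    df$qvalue <- NA_real_
    df$summit_offset <- NA_real_
  } else {
    df$name <- m[, 4]
    df$peak_score <- as.numeric(m[, 5])
    df$strand <- m[, 6]
    df$signal_value <- as.numeric(m[, 7])
    df$pvalue <- as.numeric(m[, 8])
    df$qvalue <- as.numeric(m[, 9])
    df$summit_offset <- if (dialect == "narrowPeak") as.numeric(m[, 10])
                        else NA_real_
  }
  if (any(df$end <= df$start - 1)) stop("peak with end <= start in ", path)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  peak_set(df, mark = mark, replicate = replicate)
}

empty_peaks <- function() {
  df <- data.frame(chromosome = character(), start = numeric(),
                   end = numeric(), name = character(),
                   peak_score = numeric(), strand = character(),
                   signal_value = numeric(), pvalue = numeric(),
                   qvalue = numeric(), summit_offset = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Tag a peak data.frame with mark/replicate labels
#'
#' @param peaks peak data.frame (columns chromosome/start/end at minimum)
#' @param mark mark label
#' @param replicate replicate label
#' @return same data.frame with class `peak_set` and attributes set
#' @export
peak_set <- function(peaks, mark = NA_character_, replicate = NA_character_) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(peaks)))
  attr(peaks, "mark") <- mark
  attr(peaks, "replicate") <- replicate
  class(peaks) <- unique(c("peak_set", class(peaks)))
  peaks
}

#' Write a peak table
#'
#' Inverse of [read_peaks()]: 1-based closed coordinates are shifted back
#' to BED half-open.
#'
#' @param peaks peak data.frame
#' @param path output path
#' @param dialect output dialect
#' @export
write_peaks <- function(peaks, path,
                        dialect = c("narrowPeak", "broadPeak", "bed3")) {
  dialect <- match.arg(dialect)
  fmt <- function(x, def) {
    x <- ifelse(is.na(x), def, x)
    x
  }
  out <- data.frame(peaks$chromosome, format_bed_num(peaks$start - 1),
                    format_bed_num(peaks$end))
  if (dialect != "bed3") {
    out <- cbind(out, fmt(peaks$name, "."), format_bed_num(fmt(peaks$peak_score, 0)),
                 fmt(peaks$strand, "."), fmt(peaks$signal_value, 0),
                 fmt(peaks$pvalue, -1), fmt(peaks$qvalue, -1))
    if (dialect == "narrowPeak") {
      out <- cbind(out, format_bed_num(fmt(peaks$summit_offset, -1)))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bed_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

#' Read a depth track from bedGraph
#'
#' @param path bedGraph file (chrom, start, end, depth)
#' @return data.frame `chromosome`, `start`, `end`, `depth` with 1-based
#'   closed coordinates, sorted, non-overlapping
#' @export
read_depth_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    depth = gr$score,
    stringsAsFactors = FALSE
  )
  if (any(df$depth < 0)) stop("negative depth in ", path)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a depth track as bedGraph
#'
#' @param track depth data.frame (chromosome, start, end, depth)
#' @param path output path
#' @export
write_depth_bedgraph <- function(track, path) {
  keep <- !is.na(track$depth)
  out <- data.frame(track$chromosome[keep],
                    format_bed_num(track$start[keep] - 1),
                    format_bed_num(track$end[keep]),
                    track$depth[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CGmap-style per-cytosine methylation table
#'
#' Columns: chromosome, nucleotide (C for + strand, G for -), position
#' (1-based), context (CG/CHG/CHH), dinucleotide, level, methylated count,
#' total count. The level is recomputed from the counts rather than trusted
#' from the file; sites with zero total reads are dropped (their level is
#' undefined).
#'
#' @param path CGmap TSV
#' @return data.frame `chromosome`, `position`, `strand`, `context`,
#'   `methylated_reads`, `total_reads`, `level`
#' @export
read_methylation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chromosome", "nucleotide",
                                        "position", "context",
                                        "dinucleotide", "level_file",
                                        "methylated_reads", "total_reads"))
  if (any(df$methylated_reads < 0) || any(df$total_reads < 0)) {
    stop("negative read counts in ", path)
  }
  if (any(df$methylated_reads > df$total_reads)) {
    stop("methylated count exceeds total count in ", path)
  }
  df <- df[df$total_reads > 0, , drop = FALSE]
  level <- df$methylated_reads / df$total_reads
  if (any(abs(level - df$level_file) > 1e-6)) {
    warning("stored methylation level inconsistent with counts at ",
            sum(abs(level - df$level_file) > 1e-6), " site(s); recomputed")
  }
  ctx <- toupper(df$context)
  ctx[ctx %in% c("CG", "CPG")] <- "CpG"
  if (!all(ctx %in% c("CpG", "CHG", "CHH"))) {
    stop("unrecognized methylation context(s): ",
         paste(unique(ctx[!ctx %in% c("CpG", "CHG", "CHH")]), collapse = ", "))
  }
  out <- data.frame(
    chromosome = as.character(df$chromosome),
    position = df$position,
    strand = ifelse(toupper(df$nucleotide) == "G", "-", "+"),
    context = ctx,
    methylated_reads = df$methylated_reads,
    total_reads = df$total_reads,
    level = level,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a methylation table in CGmap layout
#'
#' @param sites methylation data.frame as returned by
#'   [read_methylation_table()]
#' @param path output path
#' @export
write_methylation_table <- function(sites, path) {
  ctx <- sites$context
  ctx[ctx == "CpG"] <- "CG"
  dinuc <- ifelse(ctx == "CG", "CG", substr(ctx, 1, 2))
  out <- data.frame(
    sites$chromosome,
    ifelse(sites$strand == "-", "G", "C"),
    sites$position,
    ctx,
    dinuc,
    sprintf("%.6f", sites$level),
    sites$methylated_reads,
    sites$total_reads
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene records from a GTF
#'
#' Keeps `gene` features; the TSS is the start coordinate for + strand
#' genes and the end coordinate for - strand genes (GTF is 1-based
#' inclusive), and vice versa for the TES.
#'
#' @param path GTF file
#' @return data.frame `gene_id`, `chromosome`, `strand`, `start`, `end`,
#'   `tss`, `tes`, `tpm` (NA until an expression table is attached)
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stop("no gene features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("gene feature without gene_id in ", path)
  }
  if (anyDuplicated(gr$gene_id)) {
    dup <- unique(gr$gene_id[duplicated(gr$gene_id)])
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("gene feature without strand in ", path)
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  out <- data.frame(
    gene_id = gr$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = s,
    end = e,
    tss = ifelse(strand == "+", s, e),
    tes = ifelse(strand == "+", e, s),
    tpm = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a gene expression table
#'
#' @param path TSV with header `gene_id<TAB>TPM`
#' @return data.frame `gene_id`, `tpm`
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("gene_id", "tpm") %in% names(df))) {
    stop("expression table must have columns gene_id and TPM")
  }
  if (any(df$tpm < 0)) stop("negative TPM in ", path)
  df[, c("gene_id", "tpm")]
}

#' Attach TPM values to gene records
#'
#' @param genes gene data.frame from [read_gtf_genes()]
#' @param expression data.frame from [read_expression_tsv()]
#' @return genes with the `tpm` column filled (NA where unmeasured)
#' @export
add_expression <- function(genes, expression) {
  i <- match(genes$gene_id, expression$gene_id)
  genes$tpm <- expression$tpm[i]
  genes
}

#' Write simulated SNVs as a minimal VCF
#'
#' Emits a single-sample VCF with GT and AD fields, the two fields the
#' allele-balance reader consumes.
#'
#' @param snvs data.frame with chromosome, position, ref_reads, alt_reads
#'   (and optionally gt, default "0/1")
#' @param path output path
#' @param sample sample name for the header
#' @export
write_snv_vcf <- function(snvs, path, sample = "sim") {
  gt <- if ("gt" %in% names(snvs)) snvs$gt else rep("0/1", nrow(snvs))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- sprintf("%s\t%d\t.\tA\tG\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
                  snvs$chromosome, as.integer(snvs$position), gt,
                  as.integer(snvs$ref_reads), as.integer(snvs$alt_reads))
  writeLines(c(header, body), path)
  invisible(path)
}
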