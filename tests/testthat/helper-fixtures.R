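# Fixture builders shared across test files. Everything is generated in
# code at test time; no binary fixtures.

write_vcf_fixture <- function(path, rows) {
  # rows: data.frame chrom, pos, gt, ad (e.g. "6,6")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  body <- sprintf("%s\t%d\t.\tA\tG\t.\tPASS\t.\tGT:AD\t%s:%s",
                  rows$chrom, rows$pos, rows$gt, rows$ad)
  writeLines(c(header, body), path)
  path
}

# The canonical mixed VCF: 70 het sites at >= 10x, 20 hom sites, 10 het
# sites below 10x.
mixed_vcf_fixture <- function(path) {
  rows <- rbind(
    data.frame(chrom = "chr1", pos = seq(1000, by = 1000, length.out = 70),
               gt = "0/1",
               ad = paste(14 + seq_len(70) %% 5, 10 + seq_len(70) %% 7,
                          sep = ","),
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = seq(100000, by = 1000, length.out = 20),
               gt = rep(c("0/0", "1/1"), 10),
               ad = rep(c("25,0", "0,25"), 10), stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = seq(200000, by = 1000, length.out = 10),
               gt = "0/1", ad = "4,4", stringsAsFactors = FALSE))
  write_vcf_fixture(path, rows)
}

write_cgmap_fixture <- function(path, n_rows = 50, n_zero = 5) {
  # deterministic CGmap table; n_zero rows carry zero total reads
  set.seed(401)
  total <- c(rep(0, n_zero), sample(5:40, n_rows - n_zero, replace = TRUE))
  total <- sample(total)
  meth <- vapply(total, function(t) if (t == 0) 0L else sample(0:t, 1), 0L)
  df <- data.frame(
    chrom = "chr1",
    nuc = rep(c("C", "G"), length.out = n_rows),
    pos = seq(500, by = 100, length.out = n_rows),
    ctx = rep(c("CG", "CHG", "CHH"), length.out = n_rows),
    dinuc = "CG",
    level = ifelse(total == 0, 0, round(meth / pmax(total, 1), 6)),
    meth = meth, total = total)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(path = path, n_valid = sum(total > 0))
}

make_sites <- function(chrom, pos, meth, total, context = "CpG",
                       strand = "+") {
  data.frame(chromosome = chrom, position = pos, strand = strand,
             context = context, methylated_reads = meth,
             total_reads = total, level = meth / total,
             stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, signal = 1,
                       score = 100, name = NULL) {
  n <- length(start)
  peak_set(data.frame(
    chromosome = rep_len(chrom, n), start = start, end = end,
    name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
    peak_score = rep_len(score, n), strand = rep_len(".", n),
    signal_value = rep_len(signal, n), pvalue = rep_len(-1, n),
    qvalue = rep_len(-1, n), summit_offset = rep_len(NA_real_, n),
    stringsAsFactors = FALSE))
}

make_genes <- function(chrom, tss, tpm, strand = "+", span = 10000) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss - span)
  end <- ifelse(strand == "+", tss + span, tss)
  data.frame(gene_id = paste0("g", seq_len(n)),
             chromosome = rep_len(chrom, n), strand = strand,
             start = start, end = end, tss = tss,
             tes = ifelse(strand == "+", end, start),
             tpm = rep_len(tpm, n), stringsAsFactors = FALSE)
}

# Independent beta-binomial log-density for oracle checks: numerical
# integral of the binomial likelihood over the Beta mixing density.
oracle_lbetabinom <- function(x, n, p, rho) {
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  f <- function(q) stats::dbinom(x, n, q) * stats::dbeta(q, a, b)
  log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
}
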