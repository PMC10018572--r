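test_that("VCF reader keeps exactly the deep heterozygous biallelic sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  mixed_vcf_fixture(path)
  rec <- read_vcf_allele_depths(path, min_site_depth = 10)
  expect_equal(nrow(rec), 70)
  expect_true(all(rec$ref_reads + rec$alt_reads >= 10))
  expect_true(all(rec$ratio_alt > 0 & rec$ratio_alt < 1))
  expect_equal(rec$ratio_ref, 1 - rec$ratio_alt)
  expect_false(is.unsorted(rec$position))

  # symmetric counts below the default threshold survive a lower one
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path2, data.frame(chrom = "chr1", pos = 100,
                                      gt = "0/1", ad = "6,6"))
  rec2 <- read_vcf_allele_depths(path2, min_site_depth = 10)
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$ratio_alt, 0.5)
})

test_that("VCF reader excludes homozygous sites and flags format problems", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, data.frame(
    chrom = "chr1", pos = c(100, 200, 300),
    gt = c("1/1", "0|1", "./x"), ad = c("0,30", "15,15", "10,10")))
  expect_warning(rec <- read_vcf_allele_depths(path), "genotype")
  expect_equal(nrow(rec), 1)         # only the phased het site survives
  expect_equal(rec$position, 200)

  # a missing AD field is a hard error naming the site
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t555\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), bad)
  expect_error(read_vcf_allele_depths(bad), "chr1:555")
})

test_that("peak reader handles dialects, sorting and malformed lines", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr2\t500\t900\tpk2\t80\t.\t7.7\t-1\t-1\t200",
               "chr1\t100\t300\tpk1\t60\t.\t12.3\t-1\t-1\t100"), path)
  pk <- read_peaks(path, "narrowPeak")
  expect_equal(pk$chromosome, c("chr1", "chr2"))   # sorted on read
  expect_equal(pk$signal_value, c(12.3, 7.7))
  expect_equal(pk$peak_score, c(60, 80))
  expect_equal(pk$start, c(101, 501))              # BED -> 1-based

  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(character(0), empty)
  expect_equal(nrow(read_peaks(empty, "narrowPeak")), 0)

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\tpk1\t60\t.\t12.3\t-1\t-1\t100",
               "chr1\t400\t500\tpk2\t60\t.\t3.3"), bad)
  expect_error(read_peaks(bad, "narrowPeak"), "line 2")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  b3 <- read_peaks(bed, "bed3")
  expect_true(is.na(b3$signal_value))
})

test_that("peak round trip through narrowPeak is exact", {
  pk <- make_peaks("chr3", c(1000, 5000), c(1400, 5600),
                   signal = c(3.25, 9.5), score = c(55, 200))
  pk$summit_offset <- c(200, 300)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(pk, path, "narrowPeak")
  back <- read_peaks(path, "narrowPeak")
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$signal_value, pk$signal_value)
  expect_equal(back$peak_score, pk$peak_score)
  expect_equal(back$summit_offset, pk$summit_offset)
})

test_that("methylation reader recomputes levels and drops zero-coverage rows", {
  fx <- write_cgmap_fixture(withr::local_tempfile(fileext = ".cgmap"))
  sites <- read_methylation_table(fx$path)
  expect_equal(nrow(sites), fx$n_valid)
  expect_equal(nrow(sites), 45)
  expect_equal(sites$level, sites$methylated_reads / sites$total_reads)
  expect_setequal(unique(sites$context), c("CpG", "CHG", "CHH"))

  # a stored level inconsistent with the counts is a warning, not trust
  path <- withr::local_tempfile(fileext = ".cgmap")
  writeLines("chr1\tC\t100\tCG\tCG\t0.9\t7\t10", path)
  expect_warning(s <- read_methylation_table(path), "inconsistent")
  expect_equal(s$level, 0.7)

  neg <- withr::local_tempfile(fileext = ".cgmap")
  writeLines("chr1\tC\t100\tCG\tCG\t0.5\t-1\t10", neg)
  expect_error(read_methylation_table(neg), "negative")
})

test_that("methylation table round trip preserves counts and levels", {
  sites <- make_sites("chr1", c(100, 250, 400), c(3, 10, 0), c(10, 20, 15),
                      context = c("CpG", "CHG", "CHH"),
                      strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".cgmap")
  write_methylation_table(sites, path)
  back <- read_methylation_table(path)
  expect_equal(back$position, sites$position)
  expect_equal(back$strand, sites$strand)
  expect_equal(back$context, sites$context)
  expect_equal(back$methylated_reads, sites$methylated_reads)
  expect_equal(back$total_reads, sites$total_reads)
  expect_equal(back$level, sites$level)
})

test_that("GTF reader applies the strand convention for TSS/TES", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\tgene\t100\t500\t.\t+\t.\t",
           "gene_id \"gplus\";"),
    paste0("chr1\tsrc\tgene\t100\t500\t.\t-\t.\t",
           "gene_id \"gminus\";")), path)
  genes <- read_gtf_genes(path)
  expect_equal(genes$tss[genes$gene_id == "gplus"], 100)
  expect_equal(genes$tes[genes$gene_id == "gplus"], 500)
  expect_equal(genes$tss[genes$gene_id == "gminus"], 500)
  expect_equal(genes$tes[genes$gene_id == "gminus"], 100)

  dup <- withr::local_tempfile(fileext = ".gtf")
  writeLines(rep(paste0("chr1\tsrc\tgene\t100\t500\t.\t+\t.\t",
                        "gene_id \"gdup\";"), 2), dup)
  expect_error(read_gtf_genes(dup), "gdup")
})

test_that("depth track round trip through bedGraph is exact", {
  tr <- data.frame(chromosome = "chr1",
                   start = c(1, 50001, 120001),
                   end = c(50000, 100000, 130000),
                   depth = c(30.5, 12, 0), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_depth_bedgraph(tr, path)
  back <- read_depth_bedgraph(path)
  expect_equal(back, tr)
})

test_that("expression table reader joins TPM onto gene records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tTPM", "g1\t5.5", "g2\t0"), path)
  expr <- read_expression_tsv(path)
  genes <- make_genes("chr1", c(1000, 2000, 3000), NA)
  genes <- add_expression(genes, expr)
  expect_equal(genes$tpm, c(5.5, 0, NA))
})
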