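test_that("context summaries exclude shallow sites and report missing contexts", {
  # 100 CpGs all at level 0.5 with good coverage
  cpg <- make_sites("chr1", seq(100, by = 50, length.out = 100),
                    meth = 10, total = 20)
  s <- context_summary(cpg)
  expect_equal(s$mean_level[s$context == "CpG"], 0.5)
  expect_equal(s$n_sites[s$context == "CpG"], 100)
  # contexts with no surviving site are NA, not zero
  expect_true(is.na(s$mean_level[s$context == "CHG"]))

  # shallow sites are excluded from the means
  mix <- rbind(make_sites("chr1", 100, 4, 4),         # level 1, cov 4
               make_sites("chr1", 200, 2, 10))        # level 0.2, cov 10
  s2 <- context_summary(mix, min_cov = 10)
  expect_equal(s2$mean_level[s2$context == "CpG"], 0.2)
  expect_equal(s2$n_sites[s2$context == "CpG"], 1)

  # hand-computed three-context fixture
  fx <- rbind(make_sites("chr1", c(100, 150), c(8, 2), c(10, 10), "CpG"),
              make_sites("chr1", c(300, 350), c(1, 3), c(20, 20), "CHG"),
              make_sites("chr1", 500, 0, 15, "CHH"))
  s3 <- context_summary(fx)
  expect_equal(s3$mean_level, c(0.5, 0.1, 0), tolerance = 1e-12)
})

test_that("RRBS-exclusive sites are those WGBS misses or undercovers", {
  # twelve RRBS sites; five planted exclusive by construction:
  #   3 absent from WGBS entirely, 2 present at WGBS coverage < 10
  #   (including the archetype RRBS 70x vs WGBS 4x)
  pos <- seq(1000, by = 100, length.out = 12)
  rrbs <- make_sites("chr1", pos, meth = 5, total = 70)
  wgbs_pos <- pos[1:9]                       # drop three positions
  wgbs_cov <- c(rep(30, 7), 4, 9)            # two undercovered
  wgbs <- make_sites("chr1", wgbs_pos, meth = 2, total = wgbs_cov)
  excl <- rrbs_exclusive_sites(rrbs, wgbs, min_cov = 10)
  expect_equal(nrow(excl), 5)
  expect_setequal(excl$position, c(pos[8], pos[9], pos[10:12]))
  expect_true(all(excl$total_reads >= 10))

  # shallow RRBS sites cannot be exclusive either
  rrbs_shallow <- make_sites("chr1", pos, meth = 2, total = 8)
  expect_equal(nrow(rrbs_exclusive_sites(rrbs_shallow, wgbs)), 0)

  # self-complement is empty when everything is well covered
  expect_equal(nrow(rrbs_exclusive_sites(rrbs, rrbs)), 0)

  # non-CpG contexts are ignored by default
  rrbs_chh <- make_sites("chr1", 99999, 5, 70, context = "CHH")
  expect_equal(nrow(rrbs_exclusive_sites(rrbs_chh, wgbs)), 0)
})

test_that("exclusive-site counts move monotonically with the threshold", {
  set.seed(301)
  pos <- seq(1000, by = 100, length.out = 200)
  rrbs <- make_sites("chr1", pos, meth = 3,
                     total = sample(5:80, 200, replace = TRUE))
  wgbs <- make_sites("chr1", pos, meth = 3,
                     total = sample(2:40, 200, replace = TRUE))
  counts_wgbs <- vapply(c(5, 10, 20, 30), function(mc) {
    # threshold raised on the WGBS side only
    nrow(rrbs_exclusive_sites(rrbs[rrbs$total_reads >= 10, ], wgbs,
                              min_cov = mc))
  }, 0)
  expect_true(all(diff(counts_wgbs) >= 0))
  counts_rrbs <- vapply(c(5, 10, 20, 30), function(mc) {
    # threshold raised on the RRBS side only
    sum(rrbs$total_reads >= mc &
          !pos %in% wgbs$position[wgbs$total_reads >= 10])
  }, 0)
  expect_true(all(diff(counts_rrbs) <= 0))
})

test_that("strand merging combines CpG dyads by summing counts", {
  sites <- rbind(
    make_sites("chr1", 100, 3, 10, strand = "+"),
    make_sites("chr1", 101, 5, 10, strand = "-"),   # same dyad
    make_sites("chr1", 500, 2, 20, strand = "+"))
  merged <- merge_strands(sites)
  expect_equal(nrow(merged), 2)
  dyad <- merged[merged$position == 100, ]
  expect_equal(dyad$methylated_reads, 8)
  expect_equal(dyad$total_reads, 20)
  expect_equal(dyad$level, 0.4)
})

test_that("site merging respects the gap threshold and covers all sites", {
  # nine sites forming three regions at max_gap 200:
  #   {100,250,400}, {1000,1100}, {5000,5050,5100,5250}
  pos <- c(100, 250, 400, 1000, 1100, 5000, 5050, 5100, 5250)
  sites <- make_sites("chr1", pos, meth = 5, total = 10)
  reg <- merge_sites_to_regions(sites, max_gap = 200)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$start, c(100, 1000, 5000))
  expect_equal(reg$end, c(400, 1100, 5250))
  expect_equal(reg$n_sites, c(3, 2, 4))

  # two sites 100 bp apart merge; 10 kb apart do not
  expect_equal(nrow(merge_sites_to_regions(
    make_sites("chr1", c(100, 200), 1, 10))), 1)
  expect_equal(nrow(merge_sites_to_regions(
    make_sites("chr1", c(100, 10100), 1, 10))), 2)

  # a lone site becomes a 1-bp region; regions are disjoint and sorted
  lone <- merge_sites_to_regions(make_sites("chr1", 777, 1, 10))
  expect_equal(lone$start, lone$end)
  expect_true(all(diff(reg$start) > 0))
  expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  # every input site falls inside exactly one region
  inside <- vapply(pos, function(p) {
    sum(p >= reg$start & p <= reg$end)
  }, 0)
  expect_true(all(inside == 1))
})

test_that("regulatory overlay annotates regions with every category hit", {
  promoters <- make_peaks("chr1", 1000, 2000)
  enhancers <- make_peaks("chr1", c(1900, 5000), c(2500, 6000))
  regions <- data.frame(chromosome = "chr1",
                        start = c(1950, 5500, 9000),
                        end = c(1960, 5600, 9100),
                        n_sites = 1, mean_level = 0.5)
  ann <- overlay_regulatory(regions, promoters, enhancers)
  expect_equal(ann$annotation,
               c("promoter,enhancer", "enhancer", "none"))
  expect_equal(unname(attr(ann, "category_counts")), c(1, 2, 1))
})

test_that("simulated RRBS-exclusive promoter regions are annotated promoter", {
  spec <- karyotype_preset("ipecj2")
  ex <- simulate_expression(spec, n_genes = 1200, seed = 101)
  epi <- simulate_epigenome(ex$genes, seed = 102)
  excl <- rrbs_exclusive_sites(epi$rrbs, epi$wgbs, min_cov = 10)

  # recovery of the truth set (collisions between overlapping promoters
  # are possible but rare)
  truth_key <- with(epi$truth$rrbs_exclusive,
                    paste(chromosome, position))
  called_key <- paste(excl$chromosome, excl$position)
  expect_gt(length(intersect(called_key, truth_key)) /
              length(truth_key), 0.98)

  # promoter overlay: exclusive regions sit in promoters by construction,
  # using the true TSS windows as promoter intervals
  regions <- merge_sites_to_regions(excl, max_gap = 200)
  promoters <- make_peaks(ex$genes$chromosome,
                          pmax(1, ex$genes$tss - 1000),
                          ex$genes$tss + 1000)
  ann <- overlay_regulatory(regions, promoters,
                            make_peaks(character(0), numeric(0),
                                       numeric(0)))
  expect_gt(mean(ann$promoter), 0.95)
})
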