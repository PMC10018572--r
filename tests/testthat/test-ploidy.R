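test_that("expected allele ratios match the copy-configuration arithmetic", {
  expect_equal(expected_allele_ratios(2, 1), 0.5)
  expect_equal(expected_allele_ratios(3, 1), c(1 / 3, 2 / 3))
  expect_equal(expected_allele_ratios(4, 1), c(0.25, 0.75))
  expect_equal(expected_allele_ratios(4, 2), 0.5)
  expect_equal(expected_allele_ratios(2, 2), numeric(0))  # homozygous
  expect_equal(expected_allele_ratios(1, 0), numeric(0))  # monosomy
  expect_error(expected_allele_ratios(2, 3), "alt_copies")

  # symmetry: (c, k) and (c, c-k) give the same ratio set
  for (c_tot in 2:6) {
    for (k in seq_len(c_tot - 1)) {
      expect_equal(expected_allele_ratios(c_tot, k),
                   expected_allele_ratios(c_tot, c_tot - k))
    }
  }
})

test_that("bin_depth computes coverage-weighted means over fixed bins", {
  # constant 30x over 100 kb -> two full bins at 30
  tr <- data.frame(chromosome = "chr1", start = 1, end = 100000, depth = 30)
  b <- bin_depth(tr, 50000)
  expect_equal(b$depth, c(30, 30))

  # half of one bin at 20, half at 40 -> 30
  tr2 <- data.frame(chromosome = "chr1", start = c(1, 25001),
                    end = c(25000, 50000), depth = c(20, 40))
  expect_equal(bin_depth(tr2, 50000)$depth, 30)

  # seven intervals with gaps and a zero-depth stretch, hand-computed
  tr7 <- data.frame(
    chromosome = "chr1",
    start = c(1, 20001, 50001, 70001, 100001, 200001, 250001),
    end = c(20000, 50000, 60000, 100000, 150000, 210000, 260000),
    depth = c(10, 20, 30, 40, 50, 60, 0))
  b7 <- bin_depth(tr7, 50000)
  expect_equal(b7$depth, c(16, 37.5, 50, NA, 60, 0))
  expect_error(bin_depth(tr7, 0), "bin_size")
})

test_that("diploid baseline uses the prior list or the density mode", {
  binned <- do.call(rbind, lapply(c(ch1 = 30, ch2 = 30, ch3 = 30, ch4 = 45),
                                  function(d) NULL))
  binned <- data.frame(
    chromosome = rep(c("ch1", "ch2", "ch3", "ch4"), each = 10),
    start = 1, end = 50000,
    depth = rep(c(30, 30, 30, 45), each = 10))
  expect_equal(diploid_baseline(binned), 30, tolerance = 0.05)
  expect_equal(diploid_baseline(binned, prior_diploid = "ch4"), 45)

  sim <- simulate_wgs(karyotype_preset("ipecj2"), seed = 31)
  expect_equal(diploid_baseline(sim$depth), 30, tolerance = 0.05)
})

test_that("site log-likelihood equals an independent brute-force sum", {
  set.seed(77)
  n <- rpois(50, 40)
  alt <- rbinom(50, n, 0.33)
  rho <- 0.01
  for (ratios in list(0.5, c(1 / 3, 2 / 3), c(0.25, 0.75))) {
    got <- site_log_likelihood(alt, n, ratios, rho)
    want <- sum(vapply(seq_along(n), function(i) {
      log(mean(vapply(ratios, function(r) {
        exp(oracle_lbetabinom(alt[i], n[i], r, rho))
      }, 0)))
    }, 0))
    expect_equal(got, want, tolerance = 1e-9)
  }
  # monosomy treats observed het sites as uniform caller noise
  expect_equal(site_log_likelihood(alt, n, numeric(0)),
               sum(-log(n + 1)))
})

test_that("classification recovers simulated states and breaks ties to lower c", {
  base <- 30
  for (cfg in list(list(c(2, 1), "2:AB"), list(c(3, 1), "3:AAB"),
                   list(c(4, 2), "4:AABB"), list(c(4, 1), "4:AAAB"))) {
    u <- uniform_karyotype(cfg[[1]][1], cfg[[1]][2], length = 100e6,
                           baseline_depth = base)
    sim <- simulate_wgs(u, seed = 41)
    call <- classify_chromosome_ploidy(
      sim$snvs, median(sim$depth$depth, na.rm = TRUE), base)
    expect_equal(call$best_state, cfg[[2]])
    expect_gt(call$confidence, 0)
  }

  # monosomy: no het sites, half depth
  call1 <- classify_chromosome_ploidy(
    data.frame(ref_reads = numeric(0), alt_reads = numeric(0)), 15, base)
  expect_equal(call1$best_state, "1")

  # no evidence at all
  expect_equal(classify_chromosome_ploidy(NULL, NA, base)$best_state,
               "unknown")

  # without depth, AABB and AB have identical ratio evidence; the tie
  # falls to the smaller copy number
  u <- uniform_karyotype(4, 2, length = 100e6, baseline_depth = base)
  sim <- simulate_wgs(u, seed = 43)
  call <- classify_chromosome_ploidy(sim$snvs, NA, base)
  expect_equal(call$best_state, "2:AB")
})

test_that("confidence grows with the number of het sites", {
  u <- uniform_karyotype(3, 1, length = 400e6)
  sim <- simulate_wgs(u, seed = 51)
  conf <- vapply(c(100, 400, 1600), function(n) {
    set.seed(n)
    mean(vapply(1:10, function(i) {
      rec <- sim$snvs[sample.int(nrow(sim$snvs), n), ]
      classify_chromosome_ploidy(rec, NA, 30)$confidence
    }, 0))
  }, 0)
  expect_true(all(diff(conf) > 0))
})

test_that("segmentation finds the diploid-to-AAAB breakpoint and deserts", {
  # homogeneous diploid: exactly one segment
  u <- uniform_karyotype(2, 1, length = 100e6)
  sim <- simulate_wgs(u, seed = 61)
  seg <- segment_allele_ratio(sim$snvs, binned = sim$depth, baseline = 30,
                              chrom_length = 100e6)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "2:AB")

  # 60% diploid / 40% 4:AAAB: breakpoint within 500 kb of 60 Mb
  spec <- karyotype_preset("ipecj2")
  sim2 <- simulate_wgs(spec, seed = 62)
  rec <- sim2$snvs[sim2$snvs$chromosome == "chr2", ]
  bn <- sim2$depth[sim2$depth$chromosome == "chr2", ]
  seg2 <- segment_allele_ratio(rec, binned = bn, baseline = 30,
                               chrom_length = 100e6)
  expect_equal(seg2$state, c("2:AB", "4:AAAB"))
  expect_lt(abs(seg2$end[1] - 60e6), 5e5)

  # proximal monosomy shows up as a het desert classified "1"
  rec3 <- sim2$snvs[sim2$snvs$chromosome == "chr3", ]
  bn3 <- sim2$depth[sim2$depth$chromosome == "chr3", ]
  seg3 <- segment_allele_ratio(rec3, binned = bn3, baseline = 30,
                               chrom_length = 80e6)
  expect_equal(seg3$state[1], "1")
  expect_equal(seg3$n_sites[1], 0)
  expect_lt(abs(seg3$end[1] - 40e6), 5e5)

  # too few sites: single low-confidence segment
  few <- sim$snvs[1:30, ]
  segf <- segment_allele_ratio(few, chrom_length = 100e6, baseline = 30)
  expect_equal(nrow(segf), 1)
  expect_true(segf$low_confidence)
})

test_that("depth anomaly detection respects thresholds and length gates", {
  # constant track: nothing to report
  const <- data.frame(chromosome = "chr1",
                      start = seq(1, 50e6, 50000),
                      end = pmin(seq(1, 50e6, 50000) + 49999, 50e6),
                      depth = 30)
  expect_equal(nrow(detect_depth_anomalies(const)), 0)

  # a 0.9-Mb dip is below the 1-Mb length gate
  dip <- const
  sel <- dip$start >= 10e6 & dip$end <= 10.9e6
  dip$depth[sel] <- 10
  expect_equal(nrow(detect_depth_anomalies(dip, min_length = 1e6)), 0)
  expect_equal(detect_depth_anomalies(dip, min_length = 0.5e6)$kind, "loss")

  # the simulated 8-Mb hemizygous deletion is recovered with >= 90%
  # reciprocal overlap
  sim <- simulate_wgs(karyotype_preset("ipecj2"), seed = 71)
  an <- detect_depth_anomalies(sim$depth[sim$depth$chromosome == "chr4", ])
  expect_equal(nrow(an), 1)
  expect_equal(an$kind, "loss")
  ov <- min(an$end, 17e6) - max(an$start, 9e6 + 1) + 1
  expect_gte(ov / (an$end - an$start + 1), 0.9)
  expect_gte(ov / 8e6, 0.9)

  # duplications are reported as gains
  gain <- const
  gain$depth[gain$start >= 20e6 & gain$end <= 25e6] <- 60
  expect_equal(detect_depth_anomalies(gain)$kind, "gain")
})

test_that("whole-genome calling table is consistent with per-chromosome calls", {
  sim <- simulate_wgs(karyotype_preset("sl29"), seed = 81)
  calls <- call_ploidy_genome(sim$snvs, sim$depth)
  expect_equal(calls$chromosome, paste0("chr", 1:6))
  expect_equal(calls$best_state[calls$chromosome == "chr1"], "2:AB")
  expect_equal(calls$best_state[calls$chromosome == "chr5"], "3:AAB")
  expect_equal(calls$best_state[calls$chromosome == "chr6"], "4:AABB")
  # per-candidate log-likelihood columns are present and best is argmax
  ll_cols <- grep("^logL_", names(calls), value = TRUE)
  expect_gt(length(ll_cols), 3)
  best_col <- paste0("logL_", calls$best_state)
  for (i in seq_len(nrow(calls))) {
    expect_equal(unname(unlist(calls[i, best_col[i]])),
                 max(unlist(calls[i, ll_cols])))
  }
})

test_that("ratio histograms count reference-supporting ratios", {
  rec <- data.frame(ratio_ref = c(0.25, 0.26, 0.74, 0.5),
                    ratio_alt = c(0.75, 0.74, 0.26, 0.5))
  h <- ratio_histogram(rec, binwidth = 0.1)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$bin_mid == 0.25], 2)
})
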