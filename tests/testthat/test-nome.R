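mk_calls <- function(pos, meth, total = 10L, context = "GCH", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = context,
             n_methylated = meth, n_total = rep(total, length(pos)))
}

test_that("methylation level pools read counts rather than averaging sites", {
  calls <- mk_calls(c(100L, 150L), c(8L, 0L), total = c(10L, 10L))
  expect_equal(methylation_level(calls[1L, ], gr("chr1", 90L, 110L)), 0.8)
  calls2 <- mk_calls(c(100L, 150L), c(3L, 7L))
  expect_equal(methylation_level(calls2, gr("chr1", 1L, 1000L)), 0.5)  # 10/20
  expect_true(is.na(methylation_level(calls2, gr("chr1", 5000L, 6000L))))
  # pooled summation oracle on random calls
  set.seed(12)
  calls3 <- mk_calls(sort(sample.int(5000L, 50L)), rbinom(50L, 10L, 0.3))
  win <- gr("chr1", 1000L, 4000L)
  inw <- calls3$pos >= 1000L & calls3$pos <= 4000L
  expect_equal(methylation_level(calls3, win),
               sum(calls3$n_methylated[inw]) / sum(calls3$n_total[inw]))
})

test_that("uniform background methylation yields zero NDRs", {
  set.seed(4)
  n <- 20000L
  calls <- mk_calls(seq(5L, by = 10L, length.out = n),
                    rbinom(n, 20L, 0.1), total = 20L)
  expect_length(suppressMessages(call_ndrs(calls)), 0L)
})

test_that("a 300-bp elevated region is called as exactly one covering NDR", {
  set.seed(6)
  pos <- seq(5L, by = 10L, length.out = 2000L)
  rate <- ifelse(pos >= 10000L & pos <= 10299L, 0.8, 0.1)
  calls <- mk_calls(pos, rbinom(length(pos), 20L, rate), total = 20L)
  # the binomial tail makes in-region windows overwhelmingly significant:
  # 10 calls x depth 20 at 0.8 against background 0.1
  expect_lt(pbinom(qbinom(0.01, 200, 0.8) - 1, 200, 0.1, lower.tail = FALSE), 1e-30)
  ndrs <- suppressMessages(call_ndrs(calls))
  expect_length(ndrs, 1L)
  expect_lte(GenomicRanges::start(ndrs), 10020L)
  expect_gte(GenomicRanges::end(ndrs), 10280L)
  expect_gt(S4Vectors::mcols(ndrs)$mean_gch, S4Vectors::mcols(ndrs)$background_gch)
})

test_that("regions shorter than the 140-bp floor are suppressed", {
  set.seed(6)
  pos <- seq(5L, by = 10L, length.out = 2000L)
  rate <- ifelse(pos >= 10000L & pos <= 10099L, 0.8, 0.1)
  calls <- mk_calls(pos, rbinom(length(pos), 20L, rate), total = 20L)
  expect_length(suppressMessages(call_ndrs(calls, min_length = 140L)), 0L)
  # the same signal passes under a lower floor: monotonicity in min_length
  expect_gte(length(suppressMessages(call_ndrs(calls, min_length = 60L))), 1L)
})

test_that("NDR count is monotone in q_max", {
  b <- default_bundle()
  n_strict <- length(suppressMessages(call_ndrs(b$calls, q_max = 0.001)))
  n_default <- length(suppressMessages(call_ndrs(b$calls, q_max = 0.05)))
  expect_lte(n_strict, n_default)
})

test_that("every reported NDR exceeds background strictly and passes the floor", {
  b <- default_bundle()
  ndrs <- suppressMessages(call_ndrs(b$calls))
  expect_true(all(S4Vectors::mcols(ndrs)$mean_gch >
                  S4Vectors::mcols(ndrs)$background_gch))
  expect_true(all(GenomicRanges::width(ndrs) >= 140L))
})

test_that("peak-NDR overlap counts any shared base and honours the summit filter", {
  peaks <- gr("chr1", c(100L, 500L, 900L), c(200L, 600L, 1000L))
  ndrs <- gr("chr1", 150L, 550L)
  expect_equal(peak_ndr_overlap(peaks, ndrs)$fraction, 2 / 3)
  expect_equal(peak_ndr_overlap(peaks, ndrs[0])$fraction, 0)
  offs <- c(240, -500, 240)
  r <- peak_ndr_overlap(peaks, ndrs, signed_offsets = offs,
                        summit_window = c(140, 340))
  expect_equal(r$n_peaks, 2L)
  expect_error(peak_ndr_overlap(peaks, ndrs, signed_offsets = offs,
                                summit_window = c(10000, 20000)),
               "empty")
})

test_that("NOMe metaplot matches methylation_level for one anchor and one bin", {
  set.seed(15)
  calls <- rbind(
    mk_calls(seq(4005L, 5995L, by = 10L), rbinom(200L, 10L, 0.4)),
    mk_calls(seq(4008L, 5998L, by = 10L), rbinom(200L, 10L, 0.8), context = "HCG"))
  anchor <- tss_gr("chr1", 5000L, "+")
  mp <- nome_metaplot(calls, anchor, half_width = 1000L, bin = 2000L)
  expect_equal(mp$GCH$level,
               methylation_level(calls, gr("chr1", 4000L, 5999L), "GCH"))
  expect_equal(mp$HCG$level,
               methylation_level(calls, gr("chr1", 4000L, 5999L), "HCG"))
  # no calls in range
  far <- tss_gr("chr1", 500000L, "+")
  mp0 <- nome_metaplot(calls, far, half_width = 1000L, bin = 2000L)
  expect_true(is.na(mp0$GCH$level))
})

test_that("bound promoters show a downstream accessibility footprint", {
  b <- default_bundle()
  carriers <- b$truth$gene_id[!is.na(b$truth$ndr_start)]
  anchors <- b$tss[S4Vectors::mcols(b$tss)$gene_id %in% carriers]
  mp <- nome_metaplot(b$calls, anchors, half_width = 1000L, bin = 20L)
  ndr_bins <- mp$GCH$mid > 50 & mp$GCH$mid < 330
  flank_bins <- mp$GCH$mid < -400
  expect_gt(mean(mp$GCH$level[ndr_bins]), 3 * mean(mp$GCH$level[flank_bins]))
  # endogenous methylation is depleted near these active CpG-island TSSs
  expect_lt(mean(mp$HCG$level[abs(mp$HCG$mid) < 400]), 0.2)
})
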