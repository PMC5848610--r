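test_that("promoter windows are strand-symmetric and clipped at zero", {
  t1 <- tss_gr("chr1", 5001L, "+")           # file position 5000
  w1 <- promoter_windows(t1)
  expect_equal(GenomicRanges::start(w1), 3001L)  # 0-based [3000, 7000)
  expect_equal(GenomicRanges::end(w1), 7000L)
  t2 <- tss_gr("chr1", 501L, "+")            # file position 500
  w2 <- promoter_windows(t2)
  expect_equal(GenomicRanges::start(w2), 1L)     # left-clipped: [0, 2500)
  expect_equal(GenomicRanges::end(w2), 2500L)
  t3 <- tss_gr("chr1", 5001L, "-")
  w3 <- promoter_windows(t3)
  expect_equal(GenomicRanges::start(w3), GenomicRanges::start(w1))
  expect_equal(GenomicRanges::end(w3), GenomicRanges::end(w1))
  expect_equal(as.character(GenomicRanges::strand(w3)), "-")
})

test_that("peak categories follow the promoter > enhancer > insulator priority", {
  tss <- tss_gr("chr1", 10000L)
  enh <- gr("chr1", c(9500L, 50000L), c(10500L, 51000L))
  ins <- gr("chr1", c(50200L, 80000L), c(50800L, 80500L))
  peaks <- gr("chr1",
              c(9800L, 50100L, 80100L, 200000L),
              c(10200L, 50500L, 80400L, 200300L),
              name = c("in_prom_and_enh", "enh_and_ctcf", "ctcf_only", "nowhere"))
  ann <- suppressMessages(classify_peaks(peaks, tss, enh, ins))
  expect_equal(ann$category,
               c("promoter", "distal_enhancer", "distal_insulator", "other"))
  expect_error(classify_peaks(peaks, tss[0], enh, ins), "empty TSS")
})

test_that("classify_peaks matches a quadratic all-pairs oracle across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    peaks <- random_intervals(30L)
    tss <- tss_gr(sample(c("chr1", "chr2"), 10L, replace = TRUE),
                  sample.int(20000L, 10L),
                  sample(c("+", "-"), 10L, replace = TRUE))
    enh <- random_intervals(8L)
    ins <- random_intervals(8L)
    hw <- 1000L
    ann <- suppressMessages(suppressWarnings(
      classify_peaks(peaks, tss, enh, ins, half_width = hw)))
    expect_equal(ann$category, oracle_classify_peaks(peaks, tss, enh, ins, hw))
    # categories partition the peak set
    expect_equal(sum(table(ann$category)), length(peaks))
    # invariance under input ordering
    perm <- sample(length(peaks))
    ann2 <- suppressMessages(suppressWarnings(
      classify_peaks(peaks[perm], tss, enh, ins, half_width = hw)))
    expect_equal(ann2$category, ann$category[perm])
  }
})

test_that("nearest TSS ties break toward the 5'-most TSS", {
  tss <- tss_gr("chr1", c(900L, 1100L), gene_id = c("L", "R"))
  peaks <- gr("chr1", 951L, 1050L, name = "mid")  # summit at midpoint 1000
  ann <- suppressMessages(classify_peaks(peaks, tss))
  expect_equal(ann$nearest_tss, "L")
})

test_that("promoter classification integrates islands, binding and activity", {
  tss <- tss_gr("chr1", c(5000L, 20000L), gene_id = c("gA", "gB"))
  islands <- gr("chr1", 4500L, 5500L)
  peaks <- list(ZFX = gr("chr1", 6000L, 6400L))
  expr <- data.frame(gene_id = c("gA", "gB"), expression = c(0, 3.2))
  ps <- classify_promoters(tss, islands, peaks, expr)
  expect_equal(ps$is_cpg_island, c(TRUE, FALSE))
  expect_equal(ps$bound_ZFX, c(TRUE, FALSE))
  expect_equal(ps$is_active, c(FALSE, TRUE))  # zero expression is inactive
  expect_warning(
    classify_promoters(tss, islands, peaks,
                       data.frame(gene_id = "gA", expression = 1)),
    "missing from the expression table")
})

test_that("planted bound fraction of active CpG promoters is recovered", {
  b <- default_bundle()
  ps <- suppressWarnings(classify_promoters(
    b$tss, b$cpg_islands, b$peaks[1:2], b$de[[1L]]))
  sel <- ps$is_cpg_island & !is.na(ps$is_active) & ps$is_active
  frac <- mean(ps$bound_ZFX[sel])
  n <- sum(sel)
  # planted 0.60; allow 3 binomial standard errors
  expect_lt(abs(frac - 0.60), 3 * sqrt(0.6 * 0.4 / n) + 0.01)
  # every planted bound promoter must be recovered
  rec <- truth_compare(list(bound_genes = bound_genes(ps, "ZFX")), b$truth)
  expect_equal(rec$recall[rec$class == "binding"], 1)
})

test_that("peak set overlap handles identity, disjointness and random sets", {
  a <- gr("chr1", c(100L, 500L), c(200L, 700L))
  expect_equal(peak_set_overlap(a, a)$fraction, 1.0)
  b <- gr("chr1", c(1000L, 2000L), c(1100L, 2100L))
  expect_equal(peak_set_overlap(a, b)$fraction, 0.0)
  expect_error(peak_set_overlap(a[0], b), "empty")
  for (seed in 1:20) {
    set.seed(seed)
    x <- random_intervals(30L); y <- random_intervals(10L)
    res <- peak_set_overlap(x, y)
    expect_equal(res$n_a_shared, sum(oracle_overlaps_any(x, y)))
    expect_equal(res$n_b_shared, sum(oracle_overlaps_any(y, x)))
    # widening b never decreases the overlap fraction
    y_wide <- gr(as.character(GenomicRanges::seqnames(y)),
                 pmax(1L, GenomicRanges::start(y) - 50L),
                 GenomicRanges::end(y) + 50L)
    expect_gte(peak_set_overlap(x, y_wide)$fraction, res$fraction)
  }
})
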