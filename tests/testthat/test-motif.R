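test_that("scan_motif finds forward and reverse-complement matches", {
  h <- scan_motif("TTAGGCCTAGTT", "AGGCCTAG")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)  # 0-based offset 2
  expect_equal(h$strand, "+")
  h2 <- scan_motif("CTAGGCCT", "AGGCCTAG")  # reverse complement of the motif
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$start, 1L)
  expect_equal(h2$strand, "-")
  # overlapping occurrences are all reported
  h3 <- scan_motif("AAAAAA", "AAAA")
  expect_equal(sum(h3$strand == "+"), 3L)
})

test_that("sequence N matches no concrete motif code", {
  expect_equal(nrow(scan_motif("TTAGGCCTNGTT", "AGGCCTAG")), 0L)
  # ambiguity codes in the motif act as wildcards
  h <- scan_motif("TTAGGA", "RGGW")
  expect_true(any(h$start == 3L & h$strand == "+"))
})

test_that("scan_motif agrees with a position-by-position oracle on random sequences", {
  set.seed(42)
  motifs <- c("AGGCCTAG", "AGGCCT", "RGGYCW")
  for (r in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    m <- motifs[(r %% 3L) + 1L]
    got <- scan_motif(s, m)
    want <- oracle_scan_motif(s, m)
    o1 <- order(got$start, got$strand); o2 <- order(want$start, want$strand)
    expect_equal(got$start[o1], want$start[o2])
    expect_equal(got$strand[o1], want$strand[o2])
  }
})

test_that("total hit count is invariant under reverse complementation", {
  set.seed(9)
  for (r in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(scan_motif(s, "AGGCCTAG")), nrow(scan_motif(rc, "AGGCCTAG")))
  }
})

test_that("scrambles preserve composition, exclude trivial permutations, and are seeded", {
  sc <- scramble_motif("AGGCCTAG", n = 10L, seed = 3L)
  expect_length(sc, 10L)
  comp <- function(x) sort(strsplit(x, "")[[1L]])
  for (s in sc) {
    expect_equal(comp(s), comp("AGGCCTAG"))
    expect_false(s == "AGGCCTAG")
    expect_false(s == "CTAGGCCT")  # reverse complement of the original
  }
  expect_identical(sc, scramble_motif("AGGCCTAG", n = 10L, seed = 3L))
  expect_error(scramble_motif("AAAA"), "no valid scramble")
})

test_that("motif counts per promoter window count planted occurrences", {
  # build a toy genome with known plantings
  base <- paste(rep("ACGTT", 2000L), collapse = "")  # 10 kb, motif-free
  chars <- strsplit(base, "")[[1L]]
  plant <- function(x, at, m) { x[at:(at + nchar(m) - 1L)] <- strsplit(m, "")[[1L]]; x }
  chars <- plant(chars, 4000L, "AGGCCTAG")
  chars <- plant(chars, 5200L, "AGGCCTAG")
  chars <- plant(chars, 6500L, "CTAGGCCT")  # reverse-strand occurrence
  genome <- Biostrings::DNAStringSet(c(chrT = paste(chars, collapse = "")))
  tss <- tss_gr("chrT", 5000L, "+", gene_id = "g1")
  counts <- suppressMessages(motifs_per_promoter(tss, genome, "AGGCCTAG"))
  expect_equal(counts$n_motifs, 3L)
  counts0 <- suppressMessages(motifs_per_promoter(tss, genome, "AGGTTTAG"))
  expect_equal(counts0$n_motifs, 0L)
})

test_that("CpG-island promoters carry more motifs than non-island promoters", {
  b <- default_bundle()
  counts <- suppressMessages(motifs_per_promoter(b$tss, b$genome, b$config$motif))
  stopifnot(identical(counts$gene_id, b$truth$gene_id))
  grp <- ifelse(b$truth$is_cpg_island, "cpg", "noncpg")
  cmp <- compare_motif_groups(counts, grp)
  expect_gt(cmp$median1[cmp$group1 == "cpg"], cmp$median2[cmp$group1 == "cpg"])
  expect_lt(cmp$p_adj[cmp$group1 == "cpg" & cmp$group2 == "noncpg"], 0.05)
  # planted Poisson(4) vs Poisson(1) background rates, read off the unbound
  # promoters (bound promoters carry extra summit-recruiting motifs)
  unbound <- !b$truth$bound
  expect_equal(stats::median(counts$n_motifs[grp == "cpg" & unbound]), 4)
  expect_equal(stats::median(counts$n_motifs[grp == "noncpg" & unbound]), 1)
})

test_that("positional profiles bin, flip and conserve hits", {
  # all items exactly 240 bp downstream
  anchors <- tss_gr("chr1", c(10000L, 30000L), c("+", "-"))
  items <- data.frame(chrom = "chr1", pos = c(10240L, 29760L))
  p <- positional_profile(items, anchors, half_width = 2000L, bin = 20L)
  expect_equal(sum(p$counts), 2L)  # one in-window item per anchor
  # both offsets are +240 after the minus-strand flip
  expect_equal(p$counts[p$mid == 250], 2L)
  expect_equal(sum(p$counts > 0L), 1L)
  expect_error(positional_profile(items, anchors, half_width = 2000L, bin = 30L),
               "does not divide")
})

test_that("strand-flipped anchors mirror the profile", {
  set.seed(5)
  pos <- sort(sample.int(50000L, 40L) + 5000L)
  anchors <- tss_gr("chr1", 30000L, "+")
  items <- data.frame(chrom = "chr1", pos = pos)
  p_plus <- positional_profile(items, anchors, 2000L, 20L)
  anchors_m <- tss_gr("chr1", 30000L, "-")
  items_m <- data.frame(chrom = "chr1", pos = 2L * 30000L - pos)  # mirrored
  p_minus <- positional_profile(items_m, anchors_m, 2000L, 20L)
  expect_equal(p_plus$counts, p_minus$counts)
  expect_equal(sum(p_plus$counts), p_plus$n_hits)
})

test_that("planted summit offsets put the modal bin at +240", {
  off <- c(rep(240.5, 50), rep(-600, 3))
  p <- positional_profile(off, half_width = 2000L, bin = 20L)
  expect_true(p$modal_lo <= 240 && 240 <= p$modal_hi)
})

test_that("motif statistics over peaks report fraction, histogram and width trend", {
  set.seed(11)
  n <- 200L
  counts <- rpois(n, 2L) + 1L
  width <- 60L + counts * 40L + sample.int(20L, n, replace = TRUE)
  start <- cumsum(width + 500L)
  chars <- rep("T", max(start + width) + 600L)
  for (i in seq_len(n)) {
    at <- start[i] + as.integer(seq(10L, width[i] - 10L, length.out = counts[i]))
    for (a in at) chars[a:(a + 7L)] <- strsplit("AGGCCTAG", "")[[1L]]
  }
  genome <- Biostrings::DNAStringSet(c(chrP = paste(chars, collapse = "")))
  peaks <- gr("chrP", start, start + width - 1L)
  st <- motif_peak_stats(peaks, genome, "AGGCCTAG")
  expect_equal(st$frac_with_motif, 1.0)
  expect_equal(sum(st$per_peak$n_motifs), sum(counts))
  expect_gt(st$spearman_width, 0.5)
  # motif-free peaks
  st0 <- motif_peak_stats(peaks, genome, "AGGAATAG")
  expect_equal(st0$frac_with_motif, 0.0)
})
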