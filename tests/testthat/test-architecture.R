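test_that("summit offsets are signed downstream in the transcription direction", {
  peaks <- gr("chr1", c(5040L, 4560L), c(5440L, 4960L),
              name = c("pA", "pB"), summit_offset = c(200L, 200L))
  # summits at 5240 and 4760
  tss_p <- tss_gr("chr1", 5000L, "+", "gp")
  expect_equal(summit_offsets(peaks[1L], tss_p)$offset, 240)
  tss_m <- tss_gr("chr1", 5000L, "-", "gm")
  expect_equal(summit_offsets(peaks[2L], tss_m)$offset, 240)
})

test_that("summit offsets are equivariant under coordinate translation", {
  set.seed(2)
  peaks <- random_intervals(20L, chroms = "chr1")
  S4Vectors::mcols(peaks)$summit_offset <-
    sample.int(50L, 20L, replace = TRUE)
  tss <- tss_gr("chr1", sample.int(20000L, 8L),
                sample(c("+", "-"), 8L, replace = TRUE))
  a <- summit_offsets(peaks, tss)
  shift <- 12345L
  peaks2 <- GenomicRanges::shift(peaks, shift)
  tss2 <- GenomicRanges::shift(tss, shift)
  b <- summit_offsets(peaks2, tss2)
  expect_equal(a$offset, b$offset)
  expect_equal(a$gene_id, b$gene_id)
})

test_that("single-TSS promoter selection matches the pairwise-distance oracle", {
  tss <- tss_gr("chr1", c(10000L, 11500L, 30000L))
  kept <- select_single_tss_promoters(tss)
  expect_equal(GenomicRanges::start(kept), 30000L)  # the 1.5 kb pair drops out
  for (seed in 1:20) {
    set.seed(seed)
    t2 <- tss_gr(sample(c("chr1", "chr2"), 50L, replace = TRUE),
                 sample.int(60000L, 50L))
    kept2 <- select_single_tss_promoters(t2, 2000L)
    expect_equal(S4Vectors::mcols(kept2)$gene_id,
                 S4Vectors::mcols(t2)$gene_id[oracle_single_tss(t2, 2000L)])
  }
})

test_that("rule clustering maps offset signs to the three classes", {
  offs <- data.frame(gene_id = c("a", "b", "b", "c", "d"),
                     peak = c("p1", "p2", "p3", "p4", "p5"),
                     offset = c(240, -240, 240, -300, 20))
  cl <- cluster_promoters(offs, method = "rule")
  lab <- setNames(cl$cluster, cl$gene_id)
  expect_equal(unname(lab["a"]), "downstream_only")
  expect_equal(unname(lab["b"]), "both")
  expect_equal(unname(lab["c"]), "upstream_only")
  expect_equal(unname(lab["d"]), "both")  # inside the 50-bp dead zone
  # label assignment ignores row order
  cl2 <- cluster_promoters(offs[sample(nrow(offs)), ], method = "rule")
  expect_equal(setNames(cl2$cluster, cl2$gene_id)[names(lab)], lab)
})

test_that("kmeans clustering recovers well-separated architecture classes", {
  set.seed(8)
  mk <- function(prefix, n, sides) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(gene_id = sprintf("%s%02d", prefix, i),
                 peak = "p",
                 offset = sides * (240 + rnorm(length(sides), 0, 30)))
    }))
  }
  offs <- rbind(mk("dn", 30, 1), mk("up", 6, -1), mk("bo", 8, c(-1, 1)))
  km <- cluster_promoters(offs, method = "kmeans", seed = 4L)
  rule <- cluster_promoters(offs, method = "rule")
  m <- merge(km, rule, by = "gene_id")
  expect_gt(mean(m$cluster.x == m$cluster.y), 0.9)
  expect_identical(km, cluster_promoters(offs, method = "kmeans", seed = 4L))
})

test_that("fraction of upstream-only bound promoters stays under 10%", {
  b <- default_bundle()
  single <- select_single_tss_promoters(b$tss)
  so <- suppressMessages(summit_offsets(b$peaks[[1L]], b$tss))
  so <- so[so$gene_id %in% S4Vectors::mcols(single)$gene_id, ]
  cl <- cluster_promoters(so, method = "rule")
  expect_lt(mean(cl$cluster == "upstream_only"), 0.10)
})

test_that("metaplot reproduces constant and block signals exactly", {
  anchors <- tss_gr("chr1", c(5000L, 9000L), c("+", "-"))
  const <- gr("chr1", 1L, 20000L, value = 1.0)
  mp <- metaplot(const, anchors, half_width = 1000L, bin = 20L)
  expect_equal(mp$mean_signal, rep(1.0, 100L))
  # single plus-strand anchor, signal only on offsets [+200, +280)
  a1 <- tss_gr("chr1", 5000L, "+")
  blk <- gr("chr1", 5200L, 5279L, value = 2.0)
  mp2 <- metaplot(blk, a1, half_width = 1000L, bin = 40L)
  inside <- mp2$mid > 200 & mp2$mid < 280
  expect_equal(mp2$mean_signal[inside], rep(2.0, sum(inside)))
  expect_equal(sum(mp2$mean_signal[!inside]), 0)
  expect_error(metaplot(gr("chr1", c(1L, 50L), c(100L, 120L), value = c(1, 2)),
                        a1), "overlapping")
})

test_that("metaplot equals the per-base averaging oracle on random tracks", {
  for (seed in 1:20) {
    set.seed(seed)
    n_anchor <- 30L
    anchors <- tss_gr("chr1", sample(2000:30000, n_anchor),
                      sample(c("+", "-"), n_anchor, replace = TRUE))
    starts <- sort(sample.int(30000L, 15L))
    ends <- starts + sample.int(300L, 15L)
    keep <- c(TRUE, starts[-1L] > ends[-15L])  # enforce non-overlap
    sig <- gr("chr1", starts[keep], ends[keep],
              value = round(runif(sum(keep), 0, 5), 2))
    mp <- metaplot(sig, anchors, half_width = 400L, bin = 20L)
    expect_equal(mp$mean_signal, oracle_metaplot(sig, anchors, 400L, 20L),
                 tolerance = 1e-9)
  }
})

test_that("tag correlation is Spearman with mid-ranked ties", {
  set.seed(3)
  m <- cbind(a = rlnorm(30), b = rlnorm(30))
  m <- cbind(m, c = -m[, "a"], d = m[, "a"])
  tc <- tag_correlation(m)
  expect_equal(unname(diag(tc)), rep(1, 4))
  expect_equal(tc["a", "d"], 1)
  expect_equal(tc["a", "c"], -1)
  # definitional oracle: rank-then-Pearson
  r <- cor(rank(m[, "a"]), rank(m[, "b"]))
  expect_equal(tc["a", "b"], r, tolerance = 1e-12)
  expect_equal(tc, t(tc))
  m0 <- cbind(m[, 1:2], z = rep(5, 30))
  tc0 <- tag_correlation(m0)
  expect_true(is.na(tc0["a", "z"]))
  expect_equal(tc0["z", "z"], 1)
  expect_error(tag_correlation(m[1:2, ]), "at least 3")
})
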