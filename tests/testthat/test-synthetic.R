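test_that("the generator is byte-deterministic for a fixed seed", {
  cfg <- small_sim_config(seed = 11L)
  b1 <- suppressMessages(generate_bundle(cfg, withr::local_tempdir()))
  b2 <- suppressMessages(generate_bundle(cfg, withr::local_tempdir()))
  m1 <- tools::md5sum(b1$files)
  m2 <- tools::md5sum(b2$files)
  expect_equal(unname(m1), unname(m2))
  b3 <- suppressMessages(generate_bundle(small_sim_config(seed = 12L),
                                         withr::local_tempdir()))
  expect_false(all(unname(tools::md5sum(b3$files)) == unname(m1)))
})

test_that("every emitted file is a valid input to its reader", {
  b <- default_bundle()
  expect_s4_class(read_fasta(b$files[["genome"]]), "DNAStringSet")
  tss <- read_tss(b$files[["tss"]])
  expect_equal(length(tss), nrow(b$truth))
  expect_equal(S4Vectors::mcols(tss)$gene_id, b$truth$gene_id)
  expect_equal(GenomicRanges::start(tss), b$truth$pos)
  islands <- read_bed(b$files[["cpg_islands"]])
  expect_gt(length(islands), 0L)
  pk <- read_narrowpeak(b$files[["peaks_tf"]])
  expect_equal(length(pk), length(b$peaks[[1L]]))
  expect_false(anyNA(S4Vectors::mcols(pk)$summit_offset))
  calls <- read_methyl_calls(b$files[["methyl_calls"]])
  expect_setequal(unique(calls$context), c("GCH", "HCG"))
  sig <- read_bedgraph(b$files[["signal_tf"]])
  expect_gt(length(sig), 0L)
  de <- read_de_table(b$files[["de_single"]])
  expect_equal(sort(de$gene_id), sort(b$truth$gene_id))
})

test_that("planted DE classes are exactly recoverable from the emitted tables", {
  b <- default_bundle()
  sel <- select_de_genes(b$de[[1L]])
  expect_setequal(sel$down, b$truth$gene_id[b$truth$de_single == "down"])
  expect_setequal(sel$up, b$truth$gene_id[b$truth$de_single == "up"])
  seld <- select_de_genes(b$de$double)
  expect_setequal(seld$down, b$truth$gene_id[b$truth$de_double == "down"])
})

test_that("an unbound genome produces no promoter peaks and background DE overlap", {
  cfg <- small_sim_config(seed = 13L, frac_bound = 0, tf2_n_shared = 0L,
                          n_redundant = 0L, kd_p_down_unbound = 0.15,
                          kd_p_up_unbound = 0.15)
  b <- suppressMessages(generate_bundle(cfg, withr::local_tempdir()))
  expect_equal(sum(b$truth$bound), 0L)
  wins <- promoter_windows(b$tss)
  expect_equal(peak_set_overlap(wins, b$peaks[[1L]])$fraction, 0)
})

test_that("configuration validation rejects impossible requests", {
  expect_error(sim_config(frac_bound = 1.2), "fractions")
  expect_error(sim_config(summit_offset_mean = 3000), "half-width")
  expect_error(sim_config(motif_rate_cpg = 600), "window capacity")
  expect_error(sim_config(n_promoters = 4000L), "too many promoters")
})

test_that("truth_compare reports exact precision and recall", {
  b <- default_bundle()
  truth_bound <- b$truth$gene_id[b$truth$bound]
  perfect <- truth_compare(list(bound_genes = truth_bound), b$truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  empty <- truth_compare(list(bound_genes = character(0)), b$truth)
  expect_equal(empty$recall, 0)
  half <- truth_compare(list(bound_genes = truth_bound[1:10]), b$truth)
  expect_equal(half$recall, 10 / length(truth_bound))
  expect_error(truth_compare(list(bound_genes = "NOT_A_GENE"), b$truth),
               "unknown gene id")
})

test_that("planted motifs are inserted verbatim at their recorded offsets", {
  b <- default_bundle()
  tr <- b$truth
  checked <- 0L
  for (i in seq_len(nrow(tr))) {
    if (!nzchar(tr$motif_offsets[i])) next
    offs <- as.numeric(strsplit(tr$motif_offsets[i], ",")[[1L]])
    sgn <- if (tr$strand[i] == "-") -1 else 1
    for (o in offs) {
      center <- tr$pos[i] + sgn * o
      left <- as.integer(center - 3.5)
      s <- as.character(Biostrings::subseq(b$genome[[tr$chrom[i]]], left, left + 7L))
      expect_true(s == "AGGCCTAG" ||
                  s == as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString("AGGCCTAG"))))
      checked <- checked + 1L
    }
    if (checked > 200L) break
  }
  expect_gt(checked, 100L)
})

test_that("CpG islands are GC- and CpG-enriched against the genome background", {
  b <- default_bundle()
  isl <- b$cpg_islands[1:20]
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(
    b$genome[[as.character(GenomicRanges::seqnames(isl))[1L]]]))[, 1:4]
  gc_genome <- sum(freq[c("C", "G")]) / sum(freq)
  gc_isl <- vapply(seq_along(isl), function(i) {
    s <- Biostrings::subseq(b$genome[[as.character(GenomicRanges::seqnames(isl))[i]]],
                            GenomicRanges::start(isl)[i], GenomicRanges::end(isl)[i])
    f <- Biostrings::alphabetFrequency(s)[1:4]
    sum(f[c("C", "G")]) / sum(f)
  }, 0)
  expect_gt(mean(gc_isl), 0.60)
  expect_lt(gc_genome, 0.55)
})
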