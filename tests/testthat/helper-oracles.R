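# Shared fixtures and independent brute-force oracles.

.promarch_cache <- new.env(parent = emptyenv())

# The default synthetic bundle, generated once per test run.
default_bundle <- function() {
  if (is.null(.promarch_cache$bundle)) {
    .promarch_cache$bundle <- suppressWarnings(suppressMessages(
      generate_bundle(sim_config(seed = 101L),
                      dir = file.path(tempdir(), "promarch_default_bundle"))))
  }
  .promarch_cache$bundle
}

default_scramble_control <- function() {
  if (is.null(.promarch_cache$scramble)) {
    b <- default_bundle()
    .promarch_cache$scramble <- suppressMessages(
      scramble_control(b$tss, b$genome, b$config$motif, n = 10L, seed = 101L))
  }
  .promarch_cache$scramble
}

# A down-scaled generator configuration for fast structural tests.
small_sim_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 4.8e5L,
               n_promoters = 40L, tf2_n_shared = 8L, tf2_n_promoter_only = 1L,
               tf2_n_distal = 1L, n_redundant = 2L, n_enhancers = 8L,
               n_insulators = 8L, n_tf_distal = 4L, call_spacing = 25L,
               kd_p_down_unbound = 0.10, kd_p_up_unbound = 0.20)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand, ...)
}

tss_gr <- function(chrom, pos, strand = "+", gene_id = NULL) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L), strand = strand,
                         gene_id = gene_id %||% sprintf("G%03d", seq_along(pos)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 20000L,
                             max_width = 400L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gr(sample(chroms, n, replace = TRUE), start,
     start + sample.int(max_width, n, replace = TRUE))
}

## ---- quadratic interval oracles -----------------------------------------

# does interval i of set 1 share >= 1 bp with any interval of set 2?
oracle_overlaps_any <- function(a, b) {
  ca <- as.character(GenomicRanges::seqnames(a)); sa <- GenomicRanges::start(a)
  ea <- GenomicRanges::end(a)
  cb <- as.character(GenomicRanges::seqnames(b)); sb <- GenomicRanges::start(b)
  eb <- GenomicRanges::end(b)
  vapply(seq_along(a), function(i) {
    any(cb == ca[i] & sb <= ea[i] & eb >= sa[i])
  }, TRUE)
}

oracle_classify_peaks <- function(peaks, tss, enh, ins, half_width) {
  wins <- gr(as.character(GenomicRanges::seqnames(tss)),
             pmax(1L, GenomicRanges::start(tss) - half_width),
             GenomicRanges::start(tss) + half_width - 1L)
  in_prom <- oracle_overlaps_any(peaks, wins)
  in_enh <- oracle_overlaps_any(peaks, enh)
  in_ins <- oracle_overlaps_any(peaks, ins)
  ifelse(in_prom, "promoter",
  ifelse(in_enh, "distal_enhancer",
  ifelse(in_ins, "distal_insulator", "other")))
}

oracle_single_tss <- function(tss, half_width) {
  chrom <- as.character(GenomicRanges::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  vapply(seq_along(tss), function(i) {
    d <- abs(pos[chrom == chrom[i]] - pos[i])
    sum(d < half_width) == 1L  # itself only
  }, TRUE)
}

## ---- motif oracle --------------------------------------------------------

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(m) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(m, "")[[1L]]]), collapse = "")
}

# position-by-position matcher: a sequence base matches a motif code iff its
# identity set is contained in the code's set (so sequence N matches only N)
oracle_scan_one_strand <- function(seq_chars, motif) {
  mc <- strsplit(motif, "")[[1L]]
  L <- length(mc); n <- length(seq_chars)
  hits <- integer(0)
  if (n < L) return(hits)
  for (s in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      sc <- seq_chars[s + k - 1L]
      if (sc == "N") { if (mc[k] != "N") { ok <- FALSE; break } }
      else if (!sc %in% IUPAC_SETS[[mc[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

oracle_scan_motif <- function(sequence, motif) {
  seq_chars <- strsplit(sequence, "")[[1L]]
  fwd <- oracle_scan_one_strand(seq_chars, motif)
  rev_ <- oracle_scan_one_strand(seq_chars, oracle_revcomp(motif))
  data.frame(start = c(fwd, rev_),
             strand = rep(c("+", "-"), c(length(fwd), length(rev_))))
}

## ---- per-base metaplot oracle --------------------------------------------

oracle_metaplot <- function(signal, anchors, half_width, bin) {
  sc <- as.character(GenomicRanges::seqnames(signal))
  ss <- GenomicRanges::start(signal); se <- GenomicRanges::end(signal)
  sv <- S4Vectors::mcols(signal)$value
  ac <- as.character(GenomicRanges::seqnames(anchors))
  ap <- GenomicRanges::start(anchors)
  as_ <- as.character(GenomicRanges::strand(anchors))
  w <- 2L * half_width
  total <- numeric(w)
  offs <- seq(-half_width, half_width - 1L)
  for (i in seq_along(anchors)) {
    base <- if (as_[i] == "-") ap[i] - offs else ap[i] + offs
    m <- outer(base, ss, ">=") & outer(base, se, "<=") &
      outer(rep(ac[i], w), sc, "==")
    total <- total + as.numeric(m %*% sv)
  }
  per_base <- total / length(anchors)
  nb <- w %/% bin
  vapply(seq_len(nb), function(b) mean(per_base[((b - 1L) * bin + 1L):(b * bin)]), 0)
}
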