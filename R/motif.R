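#' IUPAC motif scanning and TSS-relative positional profiles
#'
#' The binding-site consensus handled throughout is an IUPAC string such as
#' `AGGCCTAG`; scanning is strand-aware (the reverse strand is scanned by
#' matching the reverse complement of the consensus against the forward
#' sequence) and every overlapping occurrence is reported. A sequence `N`
#' matches only the motif code `N`: an ambiguous base never satisfies a
#' concrete motif position.
#'
#' @name promarch-motif
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

validate_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1L]]
  if (length(letters) < 4L) stopf("motif must be at least 4 nt, got '%s'", motif)
  bad <- setdiff(letters, IUPAC_CODES)
  if (length(bad) > 0L) stopf("motif '%s' contains non-IUPAC letter(s): %s",
                              motif, paste(bad, collapse = ", "))
  motif
}

#' Scan one sequence for an IUPAC motif on both strands
#'
#' @param sequence A character string or `DNAString` over A/C/G/T/N.
#' @param motif IUPAC consensus string (length >= 4).
#' @return A `data.frame` with columns `start` (1-based leftmost base of the
#'   matched span on the forward sequence), `strand` (`+` for a forward match,
#'   `-` for a reverse-complement match) and `midpoint`
#'   (`start + (length - 1)/2`; half-integer for even-length motifs).
#' @export
scan_motif <- function(sequence, motif) {
  motif <- validate_motif(motif)
  subject <- if (is(sequence, "DNAString")) sequence else Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(motif)
  fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                  fixed = "subject")
  start <- c(IRanges::start(fwd), IRanges::start(rev))
  strand <- c(rep("+", length(fwd)), rep("-", length(rev)))
  o <- order(start, strand)
  data.frame(start = start[o], strand = strand[o],
             midpoint = start[o] + (nchar(motif) - 1) / 2,
             stringsAsFactors = FALSE)
}

# Scan every chromosome of a genome; returns chrom/start/strand/midpoint.
scan_genome_motif <- function(genome, motif) {
  hits <- lapply(names(genome), function(chr) {
    h <- scan_motif(genome[[chr]], motif)
    if (nrow(h) > 0L) cbind(chrom = chr, h, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), midpoint = numeric(0))
  }
  out
}

# Extract the +/- half_width window sequence around each TSS, with a margin so
# motif occurrences straddling the window edge are still found. Windows with
# more than `max_n_frac` N bases are dropped with a message.
tss_window_hits <- function(tss, genome, motif, half_width = 2000L,
                            max_n_frac = 0.1) {
  motif <- validate_motif(motif)
  len <- nchar(motif)
  chrom <- as.character(GenomicRanges::seqnames(tss))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing) > 0L) {
    stopf("genome is missing chromosome(s): %s", paste(missing, collapse = ", "))
  }
  pos <- GenomicRanges::start(tss)
  sgn <- strand_sign(GenomicRanges::strand(tss))
  gene <- S4Vectors::mcols(tss)$gene_id %||% as.character(seq_along(tss))
  res <- vector("list", length(tss))
  n_dropped <- 0L
  clipped <- logical(length(tss))
  for (i in seq_along(tss)) {
    chr_seq <- genome[[chrom[i]]]
    lo <- pos[i] - half_width - (len - 1L)
    hi <- pos[i] + half_width - 1L + (len - 1L)
    clipped[i] <- lo < 1L || hi > length(chr_seq)
    lo_c <- max(1L, lo); hi_c <- min(length(chr_seq), hi)
    win <- Biostrings::subseq(chr_seq, lo_c, hi_c)
    n_frac <- sum(Biostrings::alphabetFrequency(win)[c("N", "-", "+", ".")]) / length(win)
    if (n_frac > max_n_frac) {
      n_dropped <- n_dropped + 1L
      res[[i]] <- NULL
      next
    }
    h <- scan_motif(win, motif)
    if (nrow(h) == 0L) {
      res[[i]] <- data.frame(gene_id = character(0), offset = numeric(0),
                             strand = character(0), stringsAsFactors = FALSE)
      next
    }
    mid_abs <- h$midpoint + lo_c - 1
    off <- (mid_abs - pos[i]) * sgn[i]
    keep <- off >= -half_width & off < half_width
    res[[i]] <- data.frame(gene_id = rep(gene[i], sum(keep)), offset = off[keep],
                           strand = h$strand[keep], stringsAsFactors = FALSE)
  }
  if (n_dropped > 0L) msg("motif", "dropped %d window(s) with >%g%% N", n_dropped, 100 * max_n_frac)
  if (any(clipped)) msg("motif", "%d window(s) clipped at a chromosome end", sum(clipped))
  kept <- !vapply(res, is.null, TRUE)
  list(hits = do.call(rbind, res[kept]),
       genes = gene[kept], n_anchors = sum(kept), clipped = clipped,
       kept_idx = which(kept))
}

#' Motif occurrences per promoter window
#'
#' Counts both-strand motif occurrences whose midpoint lies within
#' +/- `half_width` of each TSS.
#'
#' @param tss TSS `GRanges`.
#' @param genome A `DNAStringSet` covering all TSS chromosomes.
#' @param motif IUPAC consensus string.
#' @param half_width Window half-width in bp.
#' @return A `data.frame` with `gene_id`, `n_motifs` and `clipped` (window
#'   truncated at a chromosome end).
#' @export
motifs_per_promoter <- function(tss, genome, motif, half_width = 2000L) {
  tw <- tss_window_hits(tss, genome, motif, half_width)
  counts <- table(factor(tw$hits$gene_id, levels = tw$genes))
  data.frame(gene_id = tw$genes, n_motifs = as.integer(counts[tw$genes]),
             clipped = tw$clipped[tw$kept_idx], stringsAsFactors = FALSE)
}

#' Compare motif counts between promoter groups
#'
#' Pairwise two-sided rank-sum tests between all groups with
#' Benjamini-Hochberg adjustment across the comparisons.
#'
#' @param counts Data frame with a `n_motifs` column.
#' @param group Factor/character vector of group labels, one per row.
#' @return A `data.frame`: `group1`, `group2`, `median1`, `median2`, `p`,
#'   `p_adj`.
#' @export
compare_motif_groups <- function(counts, group) {
  stopifnot(nrow(counts) == length(group))
  group <- as.character(group)
  levels <- sort(unique(group))
  pairs <- utils::combn(levels, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- counts$n_motifs[group == pr[1L]]
    y <- counts$n_motifs[group == pr[2L]]
    p <- if (length(x) > 0L && length(y) > 0L) {
      suppressWarnings(wilcox.test(x, y)$p.value)
    } else NA_real_
    data.frame(group1 = pr[1L], group2 = pr[2L],
               median1 = stats::median(x), median2 = stats::median(y),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' TSS-relative positional profile
#'
#' Aggregates item positions (motif midpoints, peak summits, ...) into binned
#' counts of signed offsets from stranded anchors; offsets are sign-flipped
#' for minus-strand anchors so that positive always means downstream in the
#' direction of transcription. Every anchor contributes all of its in-window
#' items (an item near two anchors counts toward both).
#'
#' @param items A `data.frame` with columns `chrom` and `pos` (1-based;
#'   half-integer midpoints allowed), or a numeric vector of precomputed
#'   signed offsets.
#' @param anchors Stranded width-1 `GRanges` (ignored when `items` is a
#'   vector of offsets, except for `n_anchors`).
#' @param half_width Window half-width in bp.
#' @param bin Bin width in bp; must divide `2 * half_width`.
#' @return An object of class `positional_profile`: list with `bin_edges`
#'   (length `n_bins + 1`), `mid` (bin centers), `counts`, `n_anchors`,
#'   `normalized` (`counts / n_anchors`), `modal_bin` (index of the first
#'   maximal bin), `modal_lo`/`modal_hi` (its edges) and `mode_kde` (mode of
#'   a Gaussian kernel density estimate of the in-window offsets, bandwidth
#'   one bin; `NA` when there are no hits).
#' @export
positional_profile <- function(items, anchors = NULL, half_width = 2000L, bin = 20L) {
  if ((2L * half_width) %% bin != 0L) {
    stopf("bin width %d does not divide window width %d", bin, 2L * half_width)
  }
  if (is.numeric(items) && is.null(dim(items))) {
    offsets <- items
    n_anchors <- if (!is.null(anchors)) length(anchors) else NA_integer_
  } else {
    stopifnot(!is.null(anchors))
    it <- data.table::data.table(chrom = as.character(items$chrom),
                                 pos = as.numeric(items$pos))
    an <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(anchors)),
      tss_pos = as.numeric(GenomicRanges::start(anchors)),
      sign_ = strand_sign(GenomicRanges::strand(anchors)))
    j <- it[an, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
    offsets <- if (nrow(j) > 0L) (j$pos - j$tss_pos) * j$sign_ else numeric(0)
    n_anchors <- length(anchors)
  }
  offsets <- offsets[offsets >= -half_width & offsets < half_width]
  edges <- seq(-half_width, half_width, by = bin)
  counts <- if (length(offsets) > 0L) {
    tabulate(floor((offsets + half_width) / bin) + 1L, nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  modal <- which.max(counts)
  mode_kde <- NA_real_
  if (length(offsets) >= 2L) {
    d <- density(offsets, bw = bin, n = 2048L, from = -half_width, to = half_width)
    mode_kde <- d$x[which.max(d$y)]
  }
  structure(list(
    bin_edges = edges, mid = edges[-length(edges)] + bin / 2,
    counts = counts, n_anchors = n_anchors,
    normalized = if (is.na(n_anchors)) counts else counts / n_anchors,
    modal_bin = modal, modal_lo = edges[modal], modal_hi = edges[modal + 1L],
    mode_kde = mode_kde, n_hits = length(offsets), bin = bin,
    half_width = half_width), class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("positional_profile: %d hits over %s anchors, %d bins of %d bp\n",
              x$n_hits, as.character(x$n_anchors), length(x$counts), x$bin))
  cat(sprintf("  modal bin [%g, %g), kde mode %.1f bp\n",
              x$modal_lo, x$modal_hi, x$mode_kde))
  invisible(x)
}

#' Positional profile of motif occurrences around TSSs
#'
#' Convenience wrapper: scans the genome windows and profiles the motif-hit
#' midpoints; windows with more than 10% ambiguous bases are dropped.
#'
#' @inheritParams motifs_per_promoter
#' @param bin Bin width in bp.
#' @return A `positional_profile`.
#' @export
motif_positional_profile <- function(tss, genome, motif, half_width = 2000L, bin = 20L) {
  tw <- tss_window_hits(tss, genome, motif, half_width)
  p <- positional_profile(tw$hits$offset, anchors = NULL,
                          half_width = half_width, bin = bin)
  p$n_anchors <- tw$n_anchors
  p$normalized <- p$counts / max(1L, tw$n_anchors)
  p
}

#' Scrambled variants of a motif
#'
#' Seeded letter permutations with the same nucleotide composition as the
#' input; permutations equal to the original or to its reverse complement are
#' rejected and redrawn.
#'
#' @param motif Consensus over A/C/G/T only.
#' @param n Number of scrambles (default 10).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Character vector of `n` scrambled motifs.
#' @export
scramble_motif <- function(motif, n = 10L, seed = 1L) {
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1L]]
  if (!all(letters %in% c("A", "C", "G", "T"))) {
    stopf("scramble_motif requires a motif over A/C/G/T, got '%s'", motif)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      found <- FALSE
      for (try in seq_len(10000L)) {
        cand <- paste(sample(letters), collapse = "")
        if (cand != motif && cand != rc) { out[i] <- cand; found <- TRUE; break }
      }
      if (!found) {
        stopf("motif '%s' has no valid scramble (all permutations equal the motif or its reverse complement)", motif)
      }
    }
    out
  })
}

#' Scrambled-motif null control for a positional profile
#'
#' Profiles the true motif and `n` scrambled variants around the same TSSs.
#' Mode locations use `bin`-bp resolution; flatness of each scrambled profile
#' is summarised as max/mean bin count at the coarser `flat_bin` resolution
#' (null counts per fine bin are too sparse at desk scale for a stable ratio).
#'
#' @inheritParams motif_positional_profile
#' @param n Number of scrambles.
#' @param seed Seed for the scramble draw.
#' @param flat_bin Bin width (bp) for the flatness ratio; must divide
#'   `2 * half_width`.
#' @return A list: `true_profile` (fine-binned `positional_profile`),
#'   `scrambles` (character vector), `scrambled_profiles` (coarse-binned
#'   profiles), `flatness` (`data.frame` of per-scramble max/mean ratios),
#'   `true_center_max` (max coarse-bin count of the true motif in the two
#'   bins spanning +/-240) and `scrambled_band_max` (max coarse-bin count
#'   over all scrambles).
#' @export
scramble_control <- function(tss, genome, motif, n = 10L, seed = 1L,
                             half_width = 2000L, bin = 20L, flat_bin = 1000L) {
  scrambles <- scramble_motif(motif, n = n, seed = seed)
  true_fine <- motif_positional_profile(tss, genome, motif, half_width, bin)
  true_coarse <- motif_positional_profile(tss, genome, motif, half_width, flat_bin)
  profs <- lapply(scrambles, function(m) {
    motif_positional_profile(tss, genome, m, half_width, flat_bin)
  })
  flat <- data.frame(
    motif = scrambles,
    max_count = vapply(profs, function(p) max(p$counts), 0),
    mean_count = vapply(profs, function(p) mean(p$counts), 0))
  flat$ratio <- ifelse(flat$mean_count > 0, flat$max_count / flat$mean_count, NA_real_)
  center <- which(true_coarse$mid > -flat_bin & true_coarse$mid < flat_bin)
  list(true_profile = true_fine, true_profile_coarse = true_coarse,
       scrambles = scrambles, scrambled_profiles = profs, flatness = flat,
       true_center_max = max(true_coarse$counts[center]),
       scrambled_band_max = max(flat$max_count))
}

#' Motif statistics over ChIP-seq peaks
#'
#' @param peaks Peak `GRanges`.
#' @param genome `DNAStringSet` with all peak chromosomes.
#' @param motif IUPAC consensus.
#' @return A list: `per_peak` (`data.frame` of peak, width, n_motifs),
#'   `histogram` (table of motif counts), `frac_with_motif` (share of peaks
#'   with >= 1 occurrence) and `spearman_width` (Spearman correlation between
#'   count and peak width; `NA` for < 3 peaks).
#' @export
motif_peak_stats <- function(peaks, genome, motif) {
  motif <- validate_motif(motif)
  len <- nchar(motif)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  n <- length(peaks)
  counts <- integer(n)
  for (i in seq_len(n)) {
    chr_seq <- genome[[chrom[i]]]
    if (is.null(chr_seq)) stopf("genome is missing chromosome '%s'", chrom[i])
    lo <- max(1L, GenomicRanges::start(peaks)[i] - (len - 1L))
    hi <- min(length(chr_seq), GenomicRanges::end(peaks)[i] + (len - 1L))
    h <- scan_motif(Biostrings::subseq(chr_seq, lo, hi), motif)
    mid_abs <- h$midpoint + lo - 1
    counts[i] <- sum(mid_abs >= GenomicRanges::start(peaks)[i] &
                     mid_abs <= GenomicRanges::end(peaks)[i])
  }
  peak_id <- S4Vectors::mcols(peaks)$name %||% as.character(seq_len(n))
  width <- GenomicRanges::width(peaks)
  rho <- if (n >= 3L) suppressWarnings(cor(counts, width, method = "spearman")) else NA_real_
  list(per_peak = data.frame(peak = peak_id, width = width, n_motifs = counts,
                             stringsAsFactors = FALSE),
       histogram = table(counts),
       frac_with_motif = if (n > 0L) mean(counts >= 1L) else NA_real_,
       spearman_width = rho)
}
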