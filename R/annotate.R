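#' Promoter window around a TSS
#'
#' The window covers +/- `half_width` bp of the TSS (strand-symmetric, clipped
#' at the chromosome start), i.e. `[pos - half_width, pos + half_width)` in
#' 0-based terms.
#'
#' @param tss A width-1 `GRanges` of TSSs (see [read_tss()]).
#' @param half_width Half-width of the window in bp (default 2000).
#' @return A `GRanges` of promoter windows carrying the TSS metadata columns.
#' @export
promoter_windows <- function(tss, half_width = 2000L) {
  stopifnot(half_width > 0L)
  pos <- GenomicRanges::start(tss)
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(1L, pos - as.integer(half_width)),
                     pos + as.integer(half_width) - 1L),
    strand = GenomicRanges::strand(tss),
    S4Vectors::mcols(tss))
}

#' Classify peaks into promoter / distal enhancer / distal insulator / other
#'
#' Priority order is promoter > distal_enhancer > distal_insulator > other:
#' any peak touching a promoter window is a promoter peak regardless of
#' chromatin marks; a distal peak overlapping an active-enhancer mark
#' (H3K27ac) is a distal enhancer; a distal peak overlapping an insulator
#' mark (CTCF) but no enhancer mark is a distal insulator. The four
#' categories partition the peak set.
#'
#' @param peaks Peak `GRanges` (summits used when `by_summit = TRUE`).
#' @param tss TSS `GRanges`; must be non-empty.
#' @param enhancer_peaks `GRanges` of enhancer-mark (H3K27ac) intervals.
#' @param insulator_peaks `GRanges` of insulator-mark (CTCF) intervals.
#' @param half_width Promoter half-width in bp.
#' @param by_summit Use only the summit base (rather than any bp of the peak)
#'   for promoter assignment.
#' @return A `data.frame` with one row per peak: `peak` (name or index),
#'   `category`, `nearest_tss` (gene id, `NA` when no TSS shares the
#'   chromosome) and `signed_offset` (summit minus TSS, downstream positive).
#' @export
classify_peaks <- function(peaks, tss, enhancer_peaks = GenomicRanges::GRanges(),
                           insulator_peaks = GenomicRanges::GRanges(),
                           half_width = 2000L, by_summit = FALSE) {
  if (length(tss) == 0L) stopf("classify_peaks: empty TSS list, annotation undefined")
  check_chrom_namespace(peaks, tss, "peak")
  windows <- promoter_windows(tss, half_width)
  spos <- suppressMessages(summit_positions(peaks))
  query <- if (by_summit) {
    point_granges(as.character(GenomicRanges::seqnames(peaks)), spos)
  } else {
    peaks
  }
  in_prom <- IRanges::overlapsAny(query, windows, ignore.strand = TRUE)
  in_enh <- IRanges::overlapsAny(peaks, enhancer_peaks, ignore.strand = TRUE)
  in_ins <- IRanges::overlapsAny(peaks, insulator_peaks, ignore.strand = TRUE)
  category <- ifelse(in_prom, "promoter",
              ifelse(in_enh, "distal_enhancer",
              ifelse(in_ins, "distal_insulator", "other")))

  nt <- nearest_tss_by_summit(peaks, spos, tss)
  peak_id <- S4Vectors::mcols(peaks)$name
  if (is.null(peak_id)) peak_id <- as.character(seq_along(peaks))
  data.frame(peak = peak_id, category = category,
             nearest_tss = nt$gene_id, signed_offset = nt$signed_offset,
             stringsAsFactors = FALSE)
}

# Nearest TSS to each summit; equidistant ties break toward the 5'-most
# (smallest-coordinate) TSS. NA when no TSS shares the chromosome.
nearest_tss_by_summit <- function(peaks, spos, tss) {
  pt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    pos = spos, idx = seq_along(peaks))
  tt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(tss)),
    tpos = GenomicRanges::start(tss),
    sign = strand_sign(GenomicRanges::strand(tss)),
    gene_id = S4Vectors::mcols(tss)$gene_id)
  j <- tt[pt, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  gene_id <- rep(NA_character_, length(peaks))
  offset <- rep(NA_real_, length(peaks))
  if (nrow(j) > 0L) {
    j[, dist := abs(pos - tpos)]
    data.table::setorderv(j, c("idx", "dist", "tpos"))
    best <- j[!duplicated(idx)]
    gene_id[best$idx] <- best$gene_id
    offset[best$idx] <- (best$pos - best$tpos) * best$sign
  }
  list(gene_id = gene_id, signed_offset = offset)
}

#' Classify promoters by CpG-island status, binding and activity
#'
#' A promoter is CpG-island if its TSS base lies inside a CpG-island interval;
#' it is bound by factor F if any F peak overlaps its +/- `half_width` window;
#' it is active if its expression exceeds `active_threshold` (`NA`, with a
#' warning, for genes absent from the expression table).
#'
#' @param tss TSS `GRanges`.
#' @param cpg_islands `GRanges` of CpG-island intervals.
#' @param peaks_by_factor Named list of peak `GRanges`, one per factor label.
#' @param expression `data.frame` with columns `gene_id` and `expression`.
#' @param active_threshold Expression strictly above this is "active".
#' @param half_width Promoter half-width in bp.
#' @return A `data.frame` with one row per TSS: `gene_id`, `chrom`, `pos`,
#'   `strand`, `is_cpg_island`, one logical `bound_<factor>` column per
#'   factor, and `is_active`.
#' @export
classify_promoters <- function(tss, cpg_islands, peaks_by_factor, expression,
                               active_threshold = 0, half_width = 2000L) {
  stopifnot(is.list(peaks_by_factor), !is.null(names(peaks_by_factor)))
  windows <- promoter_windows(tss, half_width)
  tss_points <- point_granges(as.character(GenomicRanges::seqnames(tss)),
                              GenomicRanges::start(tss))
  out <- data.frame(
    gene_id = S4Vectors::mcols(tss)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(tss)),
    pos = GenomicRanges::start(tss),
    strand = as.character(GenomicRanges::strand(tss)),
    is_cpg_island = IRanges::overlapsAny(tss_points, cpg_islands, ignore.strand = TRUE),
    stringsAsFactors = FALSE)
  for (f in names(peaks_by_factor)) {
    out[[paste0("bound_", f)]] <-
      IRanges::overlapsAny(windows, peaks_by_factor[[f]], ignore.strand = TRUE)
  }
  i <- match(out$gene_id, expression$gene_id)
  if (anyNA(i)) {
    warning(sprintf("%d gene(s) missing from the expression table; is_active set NA",
                    sum(is.na(i))), call. = FALSE)
  }
  out$expression <- expression$expression[i]
  out$is_active <- out$expression > active_threshold
  out
}

#' Gene identifiers bound by a factor
#'
#' @param promoter_status Output of [classify_promoters()].
#' @param factor Factor label (matching a `bound_<factor>` column).
#' @return Character vector of bound gene ids (a gene with several TSSs is
#'   bound if any of its promoter windows is bound).
#' @export
bound_genes <- function(promoter_status, factor) {
  col <- paste0("bound_", factor)
  if (is.null(promoter_status[[col]])) stopf("no binding column for factor '%s'", factor)
  unique(promoter_status$gene_id[promoter_status[[col]]])
}

#' Overlap between two peak sets
#'
#' @param a,b Peak `GRanges`; overlap means at least 1 shared bp.
#' @return A list: `fraction` (share of `a` overlapping >= 1 interval of `b`),
#'   `n_a`, `n_a_shared`, `n_a_unique`, `n_b`, `n_b_shared`, `n_b_unique`.
#' @export
peak_set_overlap <- function(a, b) {
  if (length(a) == 0L) stopf("peak_set_overlap: empty first peak set, fraction undefined")
  a_hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
  b_hit <- IRanges::overlapsAny(b, a, ignore.strand = TRUE)
  list(fraction = sum(a_hit) / length(a),
       n_a = length(a), n_a_shared = sum(a_hit), n_a_unique = sum(!a_hit),
       n_b = length(b), n_b_shared = sum(b_hit), n_b_unique = sum(!b_hit))
}
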