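#' Pooled methylation level in a window
#'
#' Pools read counts (sum methylated / sum total) over all calls of the given
#' context inside the window; pooling, not averaging of per-site levels.
#'
#' @param calls Methylation-call `data.frame` (see [read_methyl_calls()]).
#' @param window A single-interval `GRanges`, or a list/vector with `chrom`,
#'   `start`, `end` (1-based, closed).
#' @param context `"HCG"` (endogenous CpG methylation) or `"GCH"`
#'   (accessibility footprint).
#' @return Methylation level in \[0, 1\], or `NA` if the window has no calls.
#' @export
methylation_level <- function(calls, window, context = c("GCH", "HCG")) {
  context <- match.arg(context)
  if (is(window, "GRanges")) {
    stopifnot(length(window) == 1L)
    window <- list(chrom = as.character(GenomicRanges::seqnames(window)),
                   start = GenomicRanges::start(window),
                   end = GenomicRanges::end(window))
  }
  sel <- calls$context == context & calls$chrom == window$chrom &
    calls$pos >= window$start & calls$pos <= window$end
  if (!any(sel)) return(NA_real_)
  sum(calls$n_methylated[sel]) / sum(calls$n_total[sel])
}

# Global pooled GCH methylation rate.
global_gch_rate <- function(calls) {
  g <- calls[calls$context == "GCH", ]
  if (nrow(g) == 0L) stopf("no GCH calls")
  sum(g$n_methylated) / sum(g$n_total)
}

#' Call nucleosome-depleted regions from GCH methylation
#'
#' Slides a window along each chromosome, tests the pooled GCH counts in each
#' window against the background rate with a one-sided binomial test,
#' BH-adjusts across all tested windows, merges significant windows that
#' overlap or lie within one step of each other, trims each merged region to
#' its outermost GCH call, and reports regions of at least `min_length` bp
#' whose pooled methylation exceeds background.
#'
#' @param calls Methylation-call `data.frame`; only GCH-context rows are used.
#' @param min_length Minimum reported region length in bp (default 140).
#' @param window Sliding-window width in bp (default 100).
#' @param step Slide step in bp (default 20).
#' @param q_max BH-adjusted significance cutoff (default 0.05).
#' @param background Background GCH rate; defaults to the genome-wide pooled
#'   rate of `calls`.
#' @param min_calls Windows with fewer GCH calls are skipped (default 3).
#' @param call_alpha Per-call one-sided binomial significance level used to
#'   locate the outermost elevated calls when trimming region boundaries
#'   (default 0.01); prevents window-width slop from inflating region lengths.
#' @param support_dist Boundary calls must have another elevated call within
#'   this many bp (default 40), so a single noisy background call cannot
#'   stretch a region.
#' @return A `GRanges` of NDRs with metadata `mean_gch`, `background_gch`,
#'   `q_value` (minimum window q inside the region), `n_calls`.
#' @export
call_ndrs <- function(calls, min_length = 140L, window = 100L, step = 20L,
                      q_max = 0.05, background = NULL, min_calls = 3L,
                      call_alpha = 0.01, support_dist = 40L) {
  g <- data.table::as.data.table(calls[calls$context == "GCH", ])
  if (nrow(g) == 0L) stopf("call_ndrs: no GCH calls")
  bg <- background %||% (sum(g$n_methylated) / sum(g$n_total))
  data.table::setorderv(g, c("chrom", "pos"))
  win_list <- list()
  skipped <- 0L
  for (chr in unique(g$chrom)) {
    gc <- g[chrom == chr]
    cm <- c(0, cumsum(gc$n_methylated)); ct <- c(0, cumsum(gc$n_total))
    lo <- seq(min(gc$pos), max(min(gc$pos), max(gc$pos) - window + 1L), by = step)
    hi <- lo + window - 1L
    i0 <- findInterval(lo - 1L, gc$pos)      # calls strictly before lo
    i1 <- findInterval(hi, gc$pos)           # calls up to hi
    n_calls <- i1 - i0
    keep <- n_calls >= min_calls
    skipped <- skipped + sum(!keep)
    if (!any(keep)) next
    meth <- (cm[i1 + 1L] - cm[i0 + 1L])[keep]
    tot <- (ct[i1 + 1L] - ct[i0 + 1L])[keep]
    p <- pbinom(meth - 1L, tot, bg, lower.tail = FALSE)
    win_list[[chr]] <- data.table::data.table(
      chrom = chr, lo = lo[keep], hi = hi[keep], meth = meth, tot = tot, p = p)
  }
  if (skipped > 0L) msg("ndr", "skipped %d window(s) with < %d GCH calls", skipped, min_calls)
  if (length(win_list) == 0L) return(empty_ndr_granges(bg))
  wins <- data.table::rbindlist(win_list)
  wins$q <- p.adjust(wins$p, method = "BH")
  sig <- wins[wins$q < q_max]
  if (nrow(sig) == 0L) return(empty_ndr_granges(bg))
  sig_gr <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$lo, sig$hi), q = sig$q)
  merged <- GenomicRanges::reduce(sig_gr, min.gapwidth = step + 1L)
  # trim each merged region to its outermost significantly elevated GCH calls
  # (window-width slop would otherwise pad every region by up to `window` bp)
  res <- lapply(seq_along(merged), function(i) {
    chr <- as.character(GenomicRanges::seqnames(merged))[i]
    lo <- GenomicRanges::start(merged)[i]; hi <- GenomicRanges::end(merged)[i]
    gc <- g[chrom == chr & pos >= lo & pos <= hi]
    if (nrow(gc) == 0L) return(NULL)
    p_call <- pbinom(gc$n_methylated - 1L, gc$n_total, bg, lower.tail = FALSE)
    elev <- which(p_call < call_alpha)
    if (length(elev) >= 2L) {
      ep <- gc$pos[elev]
      gap_prev <- c(Inf, diff(ep)); gap_next <- c(diff(ep), Inf)
      elev <- elev[pmin(gap_prev, gap_next) <= support_dist]
    }
    if (length(elev) < 2L) return(NULL)
    b_lo <- gc$pos[min(elev)]; b_hi <- gc$pos[max(elev)]
    inside <- gc[gc$pos >= b_lo & gc$pos <= b_hi, ]
    qmin <- min(sig$q[sig$chrom == chr & sig$lo <= hi & sig$hi >= lo])
    data.frame(chrom = chr, start = b_lo, end = b_hi,
               mean_gch = sum(inside$n_methylated) / sum(inside$n_total),
               q_value = qmin, n_calls = nrow(inside), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty_ndr_granges(bg))
  keep <- (res$end - res$start + 1L) >= min_length & res$mean_gch > bg
  res <- res[keep, , drop = FALSE]
  GenomicRanges::GRanges(res$chrom, IRanges::IRanges(res$start, res$end),
                         mean_gch = res$mean_gch,
                         background_gch = rep(bg, nrow(res)),
                         q_value = res$q_value, n_calls = res$n_calls)
}

empty_ndr_granges <- function(bg) {
  GenomicRanges::GRanges(mean_gch = numeric(0), background_gch = numeric(0),
                         q_value = numeric(0), n_calls = integer(0))
}

#' Fraction of peaks overlapping an NDR
#'
#' Optionally restricts to peaks whose summit-to-TSS signed offset lies in a
#' window around the preferred downstream position (+240 bp by default).
#'
#' @param peaks Peak `GRanges`.
#' @param ndrs NDR `GRanges` (see [call_ndrs()]).
#' @param signed_offsets Numeric vector (parallel to `peaks`) of summit-to-TSS
#'   offsets; required when `summit_window` is given.
#' @param summit_window Length-2 numeric `c(lo, hi)` (default `c(140, 340)`)
#'   or `NULL` for no filtering.
#' @return A list: `fraction`, `n_peaks`, `n_overlapping`.
#' @export
peak_ndr_overlap <- function(peaks, ndrs, signed_offsets = NULL,
                             summit_window = NULL) {
  if (!is.null(summit_window)) {
    stopifnot(length(summit_window) == 2L)
    if (is.null(signed_offsets) || length(signed_offsets) != length(peaks)) {
      stopf("peak_ndr_overlap: signed_offsets (one per peak) required with summit_window")
    }
    keep <- !is.na(signed_offsets) & signed_offsets >= summit_window[1L] &
      signed_offsets <= summit_window[2L]
    peaks <- peaks[keep]
  }
  if (length(peaks) == 0L) stopf("peak_ndr_overlap: empty (filtered) peak set")
  hit <- IRanges::overlapsAny(peaks, ndrs, ignore.strand = TRUE)
  list(fraction = mean(hit), n_peaks = length(peaks), n_overlapping = sum(hit))
}

#' NOMe-seq metaplots around anchors
#'
#' Per-bin pooled methylation level (sum methylated / sum total across all
#' anchors and in-bin calls) for the HCG and GCH contexts separately, with
#' offsets flipped to the direction of transcription.
#'
#' @param calls Methylation-call `data.frame`.
#' @param anchors Stranded width-1 `GRanges`.
#' @param half_width Window half-width in bp (default 1000).
#' @param bin Bin width in bp.
#' @return A list with elements `HCG` and `GCH`, each a list of class
#'   `nome_metaplot`: `mid` (bin centers), `level` (pooled level per bin, `NA`
#'   where no calls), `n_calls`, `n_anchors`.
#' @export
nome_metaplot <- function(calls, anchors, half_width = 1000L, bin = 20L) {
  if ((2L * half_width) %% bin != 0L) {
    stopf("bin width %d does not divide window width %d", bin, 2L * half_width)
  }
  dt <- data.table::as.data.table(calls)
  dt$call_pos <- dt$pos
  an <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(anchors)),
    lo = as.numeric(GenomicRanges::start(anchors)) - half_width,
    hi = as.numeric(GenomicRanges::start(anchors)) + half_width,
    tss_pos = as.numeric(GenomicRanges::start(anchors)),
    sign_ = strand_sign(GenomicRanges::strand(anchors)))
  j <- dt[an, on = c("chrom", "pos>=lo", "pos<=hi"),
          allow.cartesian = TRUE, nomatch = NULL]
  nb <- (2L * half_width) %/% bin
  mids <- seq(-half_width, half_width - bin, by = bin) + bin / 2
  out <- list()
  for (ctx in c("HCG", "GCH")) {
    if (nrow(j) > 0L) {
      jc <- j[j$context == ctx]
      off <- (jc$call_pos - jc$tss_pos) * jc$sign_
      keep <- off >= -half_width & off < half_width
      jc <- jc[keep]; off <- off[keep]
    } else {
      jc <- j; off <- numeric(0)
    }
    bidx <- floor((off + half_width) / bin) + 1L
    meth <- vapply(seq_len(nb), function(b) sum(jc$n_methylated[bidx == b]), 0)
    tot <- vapply(seq_len(nb), function(b) sum(jc$n_total[bidx == b]), 0)
    out[[ctx]] <- structure(list(
      mid = mids, level = ifelse(tot > 0, meth / tot, NA_real_),
      n_calls = as.integer(tabulate(bidx, nbins = nb)),
      n_anchors = length(anchors), bin = bin, half_width = half_width),
      class = "nome_metaplot")
  }
  out
}

#' @export
print.nome_metaplot <- function(x, ...) {
  cat(sprintf("nome_metaplot: %d anchors, %d bins, mean level %.3f\n",
              x$n_anchors, length(x$mid), mean(x$level, na.rm = TRUE)))
  invisible(x)
}
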