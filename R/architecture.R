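#' Summit-to-TSS signed offsets
#'
#' One record per (peak, overlapping promoter window) pair. The offset is
#' summit minus TSS with the sign flipped for minus-strand TSSs, so positive
#' always means downstream of the TSS in the direction of transcription.
#' Peaks without a recorded summit use the interval midpoint (logged).
#'
#' @param peaks Peak `GRanges` (with `summit_offset` metadata where known).
#' @param tss TSS `GRanges`.
#' @param half_width Promoter half-width in bp.
#' @return A `data.frame`: `gene_id`, `peak`, `offset` (signed bp).
#' @export
summit_offsets <- function(peaks, tss, half_width = 2000L) {
  windows <- promoter_windows(tss, half_width)
  spos <- summit_positions(peaks)
  ov <- GenomicRanges::findOverlaps(peaks, windows, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  peak_id <- S4Vectors::mcols(peaks)$name %||% as.character(seq_along(peaks))
  sgn <- strand_sign(GenomicRanges::strand(tss))
  data.frame(
    gene_id = (S4Vectors::mcols(tss)$gene_id %||% as.character(seq_along(tss)))[si],
    peak = peak_id[qi],
    offset = (spos[qi] - GenomicRanges::start(tss)[si]) * sgn[si],
    stringsAsFactors = FALSE)
}

#' Promoters with a single TSS in their window
#'
#' Keeps a TSS iff no other TSS on the same chromosome lies closer than
#' `half_width` bp.
#'
#' @param tss TSS `GRanges`.
#' @param half_width Exclusion half-width in bp.
#' @return The kept subset of `tss`.
#' @export
select_single_tss_promoters <- function(tss, half_width = 2000L) {
  if (length(tss) == 0L) return(tss)
  chrom <- as.character(GenomicRanges::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  keep <- logical(length(tss))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    p <- pos[i]
    o <- order(p)
    ps <- p[o]
    d_prev <- c(Inf, diff(ps))
    d_next <- c(diff(ps), Inf)
    iso <- d_prev >= half_width & d_next >= half_width
    keep[i[o]] <- iso
  }
  tss[keep]
}

#' Per-promoter summit architecture
#'
#' @param offsets Output of [summit_offsets()].
#' @return A `data.frame` with one row per gene: `gene_id`, `n_peaks`,
#'   `offsets` (comma-joined), `mean_offset`.
#' @export
promoter_architectures <- function(offsets) {
  dt <- data.table::as.data.table(offsets)
  out <- dt[, list(n_peaks = .N,
                   offsets = paste(sort(offset), collapse = ","),
                   mean_offset = mean(offset)), by = "gene_id"]
  data.table::setDF(out)
  out
}

#' Cluster bound promoters into upstream / downstream / bidirectional classes
#'
#' Rule method: a promoter whose summit offsets are all below `-boundary` is
#' `upstream_only`; all above `+boundary` is `downstream_only`; anything else
#' (mixed signs, or any offset inside the +/-`boundary` dead zone around the
#' TSS) is `both`. The kmeans method clusters binned per-promoter offset
#' histograms into k = 3 groups (seeded, 10 restarts) and maps the clusters
#' to the three labels by their mean offsets.
#'
#' @param offsets Output of [summit_offsets()], restricted to the promoters
#'   of interest (typically single-TSS bound promoters).
#' @param method `"rule"` or `"kmeans"`.
#' @param boundary Dead-zone half-width in bp for the rule method.
#' @param half_width Window half-width (kmeans feature range).
#' @param bin Feature bin width for kmeans, bp; 500 keeps the +/-240 bp
#'   architecture classes in separate bins despite summit jitter.
#' @param seed Seed for the kmeans restarts.
#' @return A `data.frame`: `gene_id`, `cluster` (one of `upstream_only`,
#'   `downstream_only`, `both`).
#' @export
cluster_promoters <- function(offsets, method = c("rule", "kmeans"),
                              boundary = 50, half_width = 2000L, bin = 500L,
                              seed = 1L) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(offsets)
  if (nrow(dt) == 0L) {
    return(data.frame(gene_id = character(0), cluster = character(0)))
  }
  if (method == "rule") {
    lab <- dt[, list(cluster = {
      if (all(offset < -boundary)) "upstream_only"
      else if (all(offset > boundary)) "downstream_only"
      else "both"
    }), by = "gene_id"]
    data.table::setDF(lab)
    return(lab)
  }
  genes <- unique(dt$gene_id)
  edges <- seq(-half_width, half_width, by = bin)
  feat <- t(vapply(genes, function(g) {
    o <- dt$offset[dt$gene_id == g]
    o <- o[o >= -half_width & o < half_width]
    cnt <- tabulate(floor((o + half_width) / bin) + 1L, nbins = length(edges) - 1L)
    if (sum(cnt) > 0L) cnt / sum(cnt) else cnt  # profile shape, not depth
  }, numeric(length(edges) - 1L)))
  k <- min(3L, nrow(feat))
  km <- with_seed(seed, kmeans(feat, centers = k, nstart = 10L))
  mids <- edges[-length(edges)] + bin / 2
  center_mean <- apply(km$centers, 1L, function(w) {
    if (sum(w) == 0) 0 else sum(w * mids) / sum(w)
  })
  lab_map <- rep("both", k)
  if (k == 3L) {
    lab_map[which.min(center_mean)] <- "upstream_only"
    lab_map[which.max(center_mean)] <- "downstream_only"
  }
  data.frame(gene_id = genes, cluster = lab_map[km$cluster],
             stringsAsFactors = FALSE)
}

#' Average signal metaplot around anchors
#'
#' Per-bin mean of a (non-overlapping) piecewise-constant signal track over
#' all anchors, per-base semantics: every base of every anchor window
#' contributes, zero where the track has no value. Offsets are flipped for
#' minus-strand anchors so positive is downstream.
#'
#' @param signal `GRanges` with a `value` metadata column; intervals within
#'   the track must not overlap.
#' @param anchors Stranded width-1 `GRanges`.
#' @param half_width Window half-width in bp.
#' @param bin Bin width in bp; must divide `2 * half_width`.
#' @return A list of class `metaplot`: `mid` (bin-center offsets),
#'   `mean_signal`, `n_anchors`.
#' @export
metaplot <- function(signal, anchors, half_width = 1000L, bin = 20L) {
  if ((2L * half_width) %% bin != 0L) {
    stopf("bin width %d does not divide window width %d", bin, 2L * half_width)
  }
  if (length(signal) > 1L) {
    red <- GenomicRanges::reduce(signal, ignore.strand = TRUE)
    if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(signal))) {
      stopf("metaplot: signal track has overlapping intervals")
    }
  }
  w <- 2L * half_width
  acc <- numeric(w)
  chrom_a <- as.character(GenomicRanges::seqnames(anchors))
  pos <- GenomicRanges::start(anchors)
  sgn <- strand_sign(GenomicRanges::strand(anchors))
  chrom_s <- as.character(GenomicRanges::seqnames(signal))
  s_start <- GenomicRanges::start(signal)
  s_end <- GenomicRanges::end(signal)
  s_val <- S4Vectors::mcols(signal)$value
  for (i in seq_along(anchors)) {
    v <- numeric(w)
    # plus strand: offset d in [-hw, hw) sits at base pos + d;
    # minus strand: at base pos - d, so collect [pos-hw+1, pos+hw] and reverse
    if (sgn[i] > 0L) {
      lo <- pos[i] - half_width
      hi <- pos[i] + half_width - 1L
    } else {
      lo <- pos[i] - half_width + 1L
      hi <- pos[i] + half_width
    }
    sel <- which(chrom_s == chrom_a[i] & s_end >= lo & s_start <= hi)
    for (s in sel) {
      a <- max(s_start[s], lo); b <- min(s_end[s], hi)
      v[(a - lo + 1L):(b - lo + 1L)] <- s_val[s]
    }
    if (sgn[i] < 0L) v <- rev(v)
    acc <- acc + v
  }
  per_base <- acc / max(1L, length(anchors))
  nb <- w %/% bin
  mean_signal <- vapply(seq_len(nb), function(b) {
    mean(per_base[((b - 1L) * bin + 1L):(b * bin)])
  }, 0)
  structure(list(mid = seq(-half_width, half_width - bin, by = bin) + bin / 2,
                 mean_signal = mean_signal, n_anchors = length(anchors),
                 bin = bin, half_width = half_width), class = "metaplot")
}

#' @export
print.metaplot <- function(x, ...) {
  cat(sprintf("metaplot: %d anchors, %d bins of %d bp, mean signal %.3g\n",
              x$n_anchors, length(x$mean_signal), x$bin, mean(x$mean_signal)))
  invisible(x)
}

#' Pairwise Spearman correlation of tag counts
#'
#' @param count_matrix Numeric matrix, regions x samples (>= 3 regions).
#' @return Symmetric matrix of Spearman correlations; diagonal 1; pairs
#'   involving a zero-variance sample are `NA`.
#' @export
tag_correlation <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  if (nrow(m) < 3L) stopf("tag_correlation needs at least 3 regions")
  ns <- ncol(m)
  out <- matrix(NA_real_, ns, ns, dimnames = list(colnames(m), colnames(m)))
  diag(out) <- 1
  sds <- apply(m, 2L, stats::sd)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i != j && sds[i] > 0 && sds[j] > 0) {
        out[i, j] <- cor(m[, i], m[, j], method = "spearman")
      }
    }
  }
  out
}
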