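#' Configuration for the synthetic-data generator
#'
#' Defaults encode the data structure the pipeline is designed around: a
#' miniature genome (2 chromosomes x 2 Mb, 400 promoters) where most
#' promoters are CpG-island promoters, about 60% of the active CpG-island
#' promoters are bound by the primary factor, summits sit at N(+240, 60) bp
#' downstream of the TSS (a small minority upstream or on both sides), the
#' AGGCCTAG consensus is planted symmetrically at N(+/-240, 50), bound
#' promoters carry a nucleosome-depleted region over the +40..+340 window
#' with GCH methylation 0.7 against a 0.1 background, bound genes are
#' down-regulated preferentially on knockdown, and a second factor co-binds
#' almost all of its sites with the first (redundancy model).
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_chroms,chrom_length,n_promoters Genome scale.
#' @param half_width Promoter half-width used for capacity checks, bp.
#' @param frac_cpg_island Fraction of promoters whose TSS lies in a CpG island.
#' @param frac_active Fraction of genes with non-zero expression.
#' @param frac_bound Fraction of active CpG-island promoters bound by the
#'   primary factor.
#' @param frac_bidirectional Fraction of promoters arranged in divergent
#'   pairs (< 2 kb apart).
#' @param summit_offset_mean,summit_offset_sd Summit offset distribution, bp.
#' @param frac_upstream,frac_both Architecture mixture (remainder downstream).
#' @param motif IUPAC consensus planted (A/C/G/T only).
#' @param motif_rate_cpg,motif_rate_noncpg Poisson mean motif count per
#'   promoter window by CpG class.
#' @param motif_mix Length-2 weights for upstream/downstream placement.
#' @param motif_offset_sd SD of planted motif offsets around +/-240 bp.
#' @param peak_flank_min,peak_flank_max Summit-to-edge distances, bp.
#' @param island_halfwidth_min,island_halfwidth_max CpG-island half-widths.
#' @param ndr_frac Fraction of bound promoters carrying a planted NDR.
#' @param ndr_offset,ndr_width NDR start offset (downstream of TSS) and width.
#' @param ndr_gch,background_gch GCH methylation inside NDRs / elsewhere.
#' @param hcg_background,hcg_promoter HCG methylation away from / near active
#'   CpG-island TSSs.
#' @param call_spacing,call_depth Methylation-call grid spacing and depth.
#' @param expr_meanlog_bound,expr_meanlog_unbound,expr_sdlog Log-normal
#'   expression model.
#' @param kd_p_down_bound,kd_p_down_unbound,kd_p_up_bound,kd_p_up_unbound
#'   Knockdown response probabilities.
#' @param n_redundant Bound genes down-regulated only in the double knockdown.
#' @param tf2_n_shared,tf2_n_promoter_only,tf2_n_distal Second-factor peak
#'   composition (co-bound, promoter-only, distal).
#' @param n_enhancers,n_insulators,n_tf_distal Distal H3K27ac / CTCF / primary
#'   factor peak counts (genome totals).
#' @param tag_rho Latent correlation of the two factors' per-peak tag
#'   strengths; 0.92 makes the realized Spearman correlation of window tag
#'   sums at co-bound promoters come out near 0.85 after the zero-truncation
#'   and mixture effects of track construction.
#' @param factors Labels for the two factors.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 2e6L, n_promoters = 400L,
                       half_width = 2000L,
                       frac_cpg_island = 0.7, frac_active = 0.9, frac_bound = 0.6,
                       frac_bidirectional = 0.1,
                       summit_offset_mean = 240, summit_offset_sd = 60,
                       frac_upstream = 0.08, frac_both = 0.10,
                       motif = "AGGCCTAG",
                       motif_rate_cpg = 4, motif_rate_noncpg = 1,
                       motif_mix = c(0.5, 0.5), motif_offset_sd = 50,
                       peak_flank_min = 150L, peak_flank_max = 250L,
                       island_halfwidth_min = 400L, island_halfwidth_max = 700L,
                       ndr_frac = 0.85, ndr_offset = 40L, ndr_width = 300L,
                       ndr_gch = 0.7, background_gch = 0.1,
                       hcg_background = 0.75, hcg_promoter = 0.05,
                       call_spacing = 10L, call_depth = 20L,
                       expr_meanlog_bound = 2, expr_meanlog_unbound = 1,
                       expr_sdlog = 1,
                       kd_p_down_bound = 0.35, kd_p_down_unbound = 0.05,
                       kd_p_up_bound = 0.03, kd_p_up_unbound = 0.10,
                       n_redundant = 30L,
                       tf2_n_shared = 144L, tf2_n_promoter_only = 1L,
                       tf2_n_distal = 1L,
                       n_enhancers = 150L, n_insulators = 150L,
                       n_tf_distal = 40L,
                       tag_rho = 0.92,
                       factors = c("ZFX", "ZNF711")) {
  cfg <- as.list(environment())
  fracs <- c(frac_cpg_island, frac_active, frac_bound, frac_bidirectional,
             frac_upstream, frac_both, ndr_frac, background_gch, ndr_gch,
             hcg_background, hcg_promoter,
             kd_p_down_bound, kd_p_down_unbound, kd_p_up_bound, kd_p_up_unbound)
  if (any(fracs < 0 | fracs > 1)) stopf("sim_config: all fractions must lie in [0, 1]")
  if (frac_upstream + frac_both > 1) stopf("sim_config: architecture fractions exceed 1")
  if (summit_offset_mean >= half_width) {
    stopf("sim_config: summit_offset_mean must lie inside the promoter half-width")
  }
  len <- nchar(motif)
  capacity <- floor(2 * half_width / (len + 2L))
  if (stats::qpois(0.999, max(motif_rate_cpg, motif_rate_noncpg)) > capacity) {
    stopf("sim_config: requested motif rate exceeds window capacity (%d motifs)", capacity)
  }
  if (n_promoters / n_chroms * 4 * half_width > chrom_length) {
    stopf("sim_config: too many promoters for the chromosome length")
  }
  structure(cfg, class = "sim_config")
}

# Sample without the length-1 surprise of sample().
pick <- function(x, k) x[sample.int(length(x), k)]

# Sample n positions at least min_dist from every position in `avoid` and
# within [lo, hi].
sample_distal <- function(n, lo, hi, avoid, min_dist) {
  if (n == 0L) return(integer(0))
  avoid <- sort(avoid)
  out <- integer(0)
  for (iter in seq_len(1000L)) {
    cand <- as.integer(runif(2L * (n - length(out)) + 10L, lo, hi))
    i <- findInterval(cand, avoid)
    d_lo <- ifelse(i == 0L, Inf, cand - avoid[pmax(i, 1L)])
    d_hi <- ifelse(i == length(avoid), Inf, avoid[pmin(i + 1L, length(avoid))] - cand)
    out <- c(out, cand[d_lo >= min_dist & d_hi >= min_dist])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stopf("sample_distal: could not place %d distal positions (genome too dense)", n)
}

random_peaks <- function(chrom, summit, flank_min, flank_max, name_prefix,
                         signal = NULL) {
  n <- length(summit)
  if (n == 0L) {
    return(GenomicRanges::GRanges(
      name = character(0), score = numeric(0), signal_value = numeric(0),
      p_value = numeric(0), q_value = numeric(0), summit_offset = integer(0)))
  }
  left <- as.integer(runif(n, flank_min, flank_max + 1))
  right <- as.integer(runif(n, flank_min, flank_max + 1))
  start <- summit - left
  end <- summit + right
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = "*",
    name = sprintf("%s_%04d", name_prefix, seq_len(n)),
    score = rep(0, n),
    signal_value = signal %||% rep(1, n),
    p_value = rep(-1, n), q_value = rep(-1, n),
    summit_offset = summit - start)
}

#' Generate a complete synthetic input bundle
#'
#' Writes a miniature genome plus every pipeline input (FASTA, TSS table,
#' CpG-island BED, narrowPeak files per factor and chromatin mark, methylation
#' call table, bedGraph signal per factor, DE tables for single and double
#' knockdowns) together with the planted ground truth. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return A list: `config`, `dir`, `files` (named paths), `truth`
#'   (per-promoter ground-truth `data.frame`), and the in-memory objects
#'   (`genome`, `tss`, `cpg_islands`, `peaks` named list, `calls`,
#'   `signal` named list, `de` named list).
#' @export
generate_bundle <- function(config = sim_config(), dir = tempfile("simbundle")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, generate_bundle_impl(config, dir))
}

generate_bundle_impl <- function(cfg, dir) {
  hw <- cfg$half_width
  len <- nchar(cfg$motif)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  n_per <- cfg$n_promoters %/% cfg$n_chroms
  extra <- cfg$n_promoters - n_per * cfg$n_chroms

  ## ---- promoter layout -------------------------------------------------
  tss_tab <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    n <- n_per + (ci <= extra)
    spacing <- cfg$chrom_length / (n + 1L)
    base <- as.integer(round(spacing * seq_len(n)))
    jit <- as.integer(runif(n, -spacing / 8, spacing / 8))
    data.frame(chrom = chroms[ci], pos = base + jit,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(tss_tab)
  # divergent pairs: move a sampled promoter next to its left neighbour
  n_pairs <- floor(cfg$frac_bidirectional * n / 2)
  if (n_pairs > 0L) {
    cand <- seq(2L, n, by = 2L)
    pair_idx <- sort(pick(cand, min(n_pairs, length(cand))))
    pair_idx <- pair_idx[tss_tab$chrom[pair_idx] == tss_tab$chrom[pair_idx - 1L]]
    tss_tab$pos[pair_idx] <- tss_tab$pos[pair_idx - 1L] +
      as.integer(runif(length(pair_idx), 300, 1500))
    tss_tab$strand[pair_idx - 1L] <- "-"
    tss_tab$strand[pair_idx] <- "+"
  }
  tss_tab$gene_id <- sprintf("G%04d", seq_len(n))
  sgn <- ifelse(tss_tab$strand == "-", -1L, 1L)

  ## ---- classes ---------------------------------------------------------
  is_cpg <- logical(n); is_cpg[sample.int(n, round(cfg$frac_cpg_island * n))] <- TRUE
  active <- logical(n); active[sample.int(n, round(cfg$frac_active * n))] <- TRUE
  eligible <- which(is_cpg & active)
  bound <- logical(n)
  bound[pick(eligible, round(cfg$frac_bound * length(eligible)))] <- TRUE
  n_bound <- sum(bound)

  ## ---- architecture and summits ----------------------------------------
  arch <- rep(NA_character_, n)
  bidx <- which(bound)
  n_up <- round(cfg$frac_upstream * n_bound)
  n_both <- round(cfg$frac_both * n_bound)
  lab <- c(rep("upstream", n_up), rep("both", n_both),
           rep("downstream", n_bound - n_up - n_both))
  arch[bidx] <- sample(lab)
  summit_off <- vector("list", n)  # transcription-direction signed offsets
  for (i in bidx) {
    m <- cfg$summit_offset_mean; s <- cfg$summit_offset_sd
    summit_off[[i]] <- switch(arch[i],
      downstream = round(rnorm(1L, m, s)),
      upstream = round(rnorm(1L, -m, s)),
      both = round(c(rnorm(1L, -m, s), rnorm(1L, m, s))))
  }

  ## ---- genome sequence --------------------------------------------------
  seqs <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
  })
  names(seqs) <- chroms
  # CG-rich CpG islands around CpG-island TSSs
  island_tab <- NULL
  for (i in which(is_cpg)) {
    half <- as.integer(runif(1L, cfg$island_halfwidth_min, cfg$island_halfwidth_max))
    lo <- max(1L, tss_tab$pos[i] - half)
    hi <- min(cfg$chrom_length, tss_tab$pos[i] + half)
    w <- hi - lo + 1L
    isl <- sample(c("A", "C", "G", "T"), w, replace = TRUE,
                  prob = c(0.175, 0.325, 0.325, 0.175))
    cg <- sample.int(w - 1L, round(0.06 * w))
    isl[cg] <- "C"; isl[cg + 1L] <- "G"
    seqs[[tss_tab$chrom[i]]][lo:hi] <- isl
    island_tab <- rbind(island_tab, data.frame(
      chrom = tss_tab$chrom[i], start = lo, end = hi, gene_id = tss_tab$gene_id[i]))
  }

  ## ---- motif planting ---------------------------------------------------
  motif_chars <- strsplit(toupper(cfg$motif), "")[[1L]]
  motif_rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[motif_chars])
  motif_truth <- vector("list", n)
  # scrub spurious exact occurrences of the consensus from every promoter
  # window first (windows of divergent pairs overlap, so scrubbing after
  # planting would destroy a neighbour's planted sites)
  for (i in seq_len(n)) {
    chr <- tss_tab$chrom[i]; p <- tss_tab$pos[i]
    lo <- max(1L, p - hw - len); hi <- min(cfg$chrom_length, p + hw + len)
    for (pass in 1:10) {
      win <- paste(seqs[[chr]][lo:hi], collapse = "")
      h <- scan_motif(win, cfg$motif)
      if (nrow(h) == 0L) break
      for (st in h$start) {
        seqs[[chr]][(lo + st - 1L):(lo + st + len - 2L)] <-
          sample(c("A", "C", "G", "T"), len, replace = TRUE)
      }
    }
  }
  used <- lapply(chroms, function(x) integer(0))  # planted spans per chrom
  names(used) <- chroms
  for (i in seq_len(n)) {
    chr <- tss_tab$chrom[i]; p <- tss_tab$pos[i]
    placed <- numeric(0)
    plant_at <- function(off) {
      off <- max(-hw + len, min(hw - len, off))
      left <- as.integer(round(p + sgn[i] * off - (len - 1) / 2))
      if (left < 1L || left + len - 1L > cfg$chrom_length) return(FALSE)
      span <- left:(left + len - 1L)
      if (any(span %in% used[[chr]])) return(FALSE)
      ins <- if (runif(1L) < 0.5) motif_chars else motif_rc
      seqs[[chr]][span] <<- ins
      used[[chr]] <<- c(used[[chr]], span)
      placed <<- c(placed, (left + (len - 1) / 2 - p) * sgn[i])
      TRUE
    }
    # the consensus recruits the factor: every planted summit sits on a motif
    if (bound[i]) {
      for (o in summit_off[[i]]) plant_at(o + round(rnorm(1L, 0, 8)))
    }
    rate <- if (is_cpg[i]) cfg$motif_rate_cpg else cfg$motif_rate_noncpg
    for (j in seq_len(rpois(1L, rate))) {
      for (try in 1:50) {
        side <- sample(c(-1, 1), 1L, prob = cfg$motif_mix)
        off <- side * rnorm(1L, cfg$summit_offset_mean, cfg$motif_offset_sd)
        if (plant_at(off)) break
      }
    }
    motif_truth[[i]] <- placed
  }

  ## ---- factor peaks -----------------------------------------------------
  all_pos_by_chrom <- split(tss_tab$pos, tss_tab$chrom)
  peak_rows <- list()
  for (i in bidx) {
    for (o in summit_off[[i]]) {
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = tss_tab$chrom[i], summit = tss_tab$pos[i] + sgn[i] * o,
        gene_id = tss_tab$gene_id[i], offset = o, stringsAsFactors = FALSE)
    }
  }
  if (is.null(prom_peaks <- do.call(rbind, peak_rows))) {
    prom_peaks <- data.frame(chrom = character(0), summit = integer(0),
                             gene_id = character(0), offset = numeric(0))
  }
  # distal marks: enhancers (H3K27ac), insulators (CTCF), plus distal TF peaks
  distal_one_chrom <- function(n_needed, chrom) {
    sample_distal(n_needed, 5000L, cfg$chrom_length - 5000L,
                  all_pos_by_chrom[[chrom]], 2L * hw + 1500L)
  }
  n_enh_per <- cfg$n_enhancers %/% cfg$n_chroms
  n_ins_per <- cfg$n_insulators %/% cfg$n_chroms
  n_tfd_per <- cfg$n_tf_distal %/% cfg$n_chroms
  enh_list <- list(); ins_list <- list(); tfd_list <- list()
  for (ch in chroms) {
    ep <- distal_one_chrom(n_enh_per, ch)
    n_ins_in_enh <- min(length(ep), n_ins_per %/% 3L)
    ip_alone <- distal_one_chrom(n_ins_per - n_ins_in_enh, ch)
    ins_in_enh <- pick(ep, n_ins_in_enh)
    # distal TF peaks: some at enhancers, some at insulators, some elsewhere
    n_at_enh <- min(length(ep), n_tfd_per %/% 3L)
    n_at_ins <- min(length(ip_alone), n_tfd_per %/% 4L)
    tfd <- distal_one_chrom(n_tfd_per - n_at_enh - n_at_ins, ch)
    enh_list[[ch]] <- data.frame(chrom = ch, summit = ep)
    ins_list[[ch]] <- data.frame(chrom = ch, summit = c(ins_in_enh, ip_alone))
    tfd_list[[ch]] <- data.frame(
      chrom = ch, summit = c(pick(ep, n_at_enh), pick(ip_alone, n_at_ins), tfd))
  }
  enh_tab <- do.call(rbind, enh_list)
  ins_tab <- do.call(rbind, ins_list)
  tfd_tab <- do.call(rbind, tfd_list)
  # distal factor peaks are also recruited by the consensus
  for (r in seq_len(nrow(tfd_tab))) {
    left <- tfd_tab$summit[r] - (len %/% 2L - 1L)
    if (left < 1L || left + len - 1L > cfg$chrom_length) next
    ins <- if (runif(1L) < 0.5) motif_chars else motif_rc
    seqs[[tfd_tab$chrom[r]]][left:(left + len - 1L)] <- ins
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms

  tag_z <- rnorm(nrow(prom_peaks))
  tf_signal <- exp(log(20) + 1 * tag_z)
  peaks_tf <- random_peaks(
    c(prom_peaks$chrom, tfd_tab$chrom), c(prom_peaks$summit, tfd_tab$summit),
    cfg$peak_flank_min, cfg$peak_flank_max, cfg$factors[1L],
    signal = c(tf_signal, exp(log(20) + rnorm(nrow(tfd_tab)))))
  peaks_enh <- random_peaks(enh_tab$chrom, enh_tab$summit, 400L, 750L, "H3K27ac")
  peaks_ins <- random_peaks(ins_tab$chrom, ins_tab$summit, 100L, 200L, "CTCF")

  ## ---- second factor ----------------------------------------------------
  if (cfg$tf2_n_shared > 0L && cfg$tf2_n_shared >= n_bound) {
    stopf("sim_config: tf2_n_shared (%d) must be below the number of bound promoters (%d)",
          cfg$tf2_n_shared, n_bound)
  }
  shared_idx <- pick(seq_len(nrow(prom_peaks)), cfg$tf2_n_shared)
  tf2_rows <- prom_peaks[shared_idx, ]
  tf2_summit <- tf2_rows$summit + as.integer(round(rnorm(nrow(tf2_rows), 0, 20)))
  tf2_genes <- tf2_rows$gene_id
  # promoter-only sites: active promoters not bound by the first factor
  po_pool <- which(active & !bound)
  po <- pick(po_pool, cfg$tf2_n_promoter_only)
  po_summit <- tss_tab$pos[po] + sgn[po] * as.integer(round(rnorm(length(po), cfg$summit_offset_mean, cfg$summit_offset_sd)))
  d2 <- distal_one_chrom(cfg$tf2_n_distal, chroms[1L])
  z2 <- cfg$tag_rho * tag_z[shared_idx] +
    sqrt(1 - cfg$tag_rho^2) * rnorm(length(shared_idx))
  tf2_signal <- exp(log(12) + 1 * z2)
  peaks_tf2 <- random_peaks(
    c(tf2_rows$chrom, tss_tab$chrom[po], rep(chroms[1L], length(d2))),
    c(tf2_summit, po_summit, d2),
    cfg$peak_flank_min - 25L, cfg$peak_flank_max - 25L, cfg$factors[2L],
    signal = c(tf2_signal, exp(log(12) + rnorm(length(po) + length(d2)))))

  ## ---- signal tracks -----------------------------------------------------
  triangle_track <- function(peaks) {
    if (length(peaks) == 0L) return(GenomicRanges::GRanges(value = numeric(0)))
    sp <- GenomicRanges::start(peaks) + S4Vectors::mcols(peaks)$summit_offset
    h <- S4Vectors::mcols(peaks)$signal_value
    rows <- data.table::rbindlist(lapply(seq_along(peaks), function(i) {
      d <- -200:199
      data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(peaks))[i],
        pos = sp[i] + d,
        v = round(h[i] * (1 - abs(d) / 200), 4))
    }))
    rows <- rows[pos >= 1L]
    agg <- rows[, list(v = max(v)), by = c("chrom", "pos")]
    data.table::setorderv(agg, c("chrom", "pos"))
    # compress runs of equal value at adjacent positions
    brk <- c(TRUE, agg$chrom[-1L] != agg$chrom[-nrow(agg)] |
               agg$pos[-1L] != agg$pos[-nrow(agg)] + 1L |
               agg$v[-1L] != agg$v[-nrow(agg)])
    gid <- cumsum(brk)
    blocks <- agg[, list(chrom = chrom[1L], start = min(pos), end = max(pos),
                         value = v[1L]), by = list(gid = gid)]
    GenomicRanges::GRanges(blocks$chrom,
                           IRanges::IRanges(blocks$start, blocks$end),
                           value = blocks$value)
  }
  signal_tf <- triangle_track(peaks_tf)
  # the second factor shows weak, correlated enrichment at first-factor sites
  # even where it has no called peak (sub-threshold binding)
  weak_idx <- setdiff(seq_len(nrow(prom_peaks)), shared_idx)
  z2w <- cfg$tag_rho * tag_z[weak_idx] +
    sqrt(1 - cfg$tag_rho^2) * rnorm(length(weak_idx))
  weak_bumps <- random_peaks(prom_peaks$chrom[weak_idx], prom_peaks$summit[weak_idx],
                             cfg$peak_flank_min - 25L, cfg$peak_flank_max - 25L,
                             "sub", signal = 0.25 * exp(log(12) + z2w))
  signal_tf2 <- triangle_track(c(peaks_tf2, weak_bumps))

  ## ---- NDRs and methylation calls ---------------------------------------
  ndr_carrier <- logical(n)
  ndr_carrier[pick(bidx, round(cfg$ndr_frac * n_bound))] <- TRUE
  ndr_lo <- ifelse(ndr_carrier,
                   pmin(tss_tab$pos + sgn * cfg$ndr_offset,
                        tss_tab$pos + sgn * (cfg$ndr_offset + cfg$ndr_width - 1L)),
                   NA_integer_)
  ndr_hi <- ifelse(ndr_carrier,
                   pmax(tss_tab$pos + sgn * cfg$ndr_offset,
                        tss_tab$pos + sgn * (cfg$ndr_offset + cfg$ndr_width - 1L)),
                   NA_integer_)
  call_list <- list()
  for (ch in chroms) {
    gpos <- seq(5L, cfg$chrom_length, by = cfg$call_spacing)
    rate <- rep(cfg$background_gch, length(gpos))
    for (i in which(ndr_carrier & tss_tab$chrom == ch)) {
      rate[gpos >= ndr_lo[i] & gpos <= ndr_hi[i]] <- cfg$ndr_gch
    }
    hpos <- gpos + 3L
    hrate <- rep(cfg$hcg_background, length(hpos))
    for (i in which(is_cpg & active & tss_tab$chrom == ch)) {
      hrate[hpos >= tss_tab$pos[i] - 500L & hpos <= tss_tab$pos[i] + 500L] <- cfg$hcg_promoter
    }
    call_list[[ch]] <- data.table::data.table(
      chrom = ch, pos = c(gpos, hpos), strand = "+",
      context = rep(c("GCH", "HCG"), c(length(gpos), length(hpos))),
      n_methylated = c(rbinom(length(gpos), cfg$call_depth, rate),
                       rbinom(length(hpos), cfg$call_depth, hrate)),
      n_total = cfg$call_depth)
  }
  calls <- data.table::setDF(data.table::rbindlist(call_list))

  ## ---- expression and knockdown DE ---------------------------------------
  expression <- numeric(n)
  expression[active & bound] <- rlnorm(sum(active & bound),
                                       cfg$expr_meanlog_bound, cfg$expr_sdlog)
  expression[active & !bound] <- rlnorm(sum(active & !bound),
                                        cfg$expr_meanlog_unbound, cfg$expr_sdlog)
  p_down <- ifelse(bound, cfg$kd_p_down_bound, cfg$kd_p_down_unbound)
  p_up <- ifelse(bound, cfg$kd_p_up_bound, cfg$kd_p_up_unbound)
  u <- runif(n)
  de_status <- ifelse(u < p_down, "down", ifelse(u < p_down + p_up, "up", "none"))
  de_status[!active] <- "none"
  draw_de <- function(status) {
    nn <- length(status)
    lfc <- rnorm(nn, 0, 0.15)
    lfc <- pmax(pmin(lfc, 0.55), -0.55)
    fdr <- runif(nn, 0.1, 1)
    is_d <- status == "down"; is_u <- status == "up"
    lfc[is_d] <- -(0.7 + stats::rexp(sum(is_d), 1 / 0.8))
    lfc[is_u] <- 0.7 + stats::rexp(sum(is_u), 1 / 0.8)
    fdr[is_d | is_u] <- runif(sum(is_d | is_u), 0, 0.04)
    list(log2fc = lfc, fdr = fdr)
  }
  de1 <- draw_de(de_status)
  # second factor alone barely changes the transcriptome
  de2_status <- rep("none", n)
  de2_status[pick(which(active), min(5L, sum(active)))] <- "down"
  de2 <- draw_de(de2_status)
  # double knockdown: single-KD responses plus redundancy-only genes
  redundant_pool <- which(bound & de_status == "none" & de2_status == "none")
  if (length(redundant_pool) < cfg$n_redundant) {
    stopf("sim_config: n_redundant (%d) exceeds available bound null genes (%d)",
          cfg$n_redundant, length(redundant_pool))
  }
  redundant <- logical(n)
  redundant[pick(redundant_pool, cfg$n_redundant)] <- TRUE
  dd_status <- de_status
  dd_status[de2_status == "down"] <- "down"
  dd_status[redundant] <- "down"
  ded <- draw_de(dd_status)
  de_single <- data.frame(gene_id = tss_tab$gene_id, expression = expression,
                          log2fc = de1$log2fc, fdr = de1$fdr)
  de_single2 <- data.frame(gene_id = tss_tab$gene_id, expression = expression,
                           log2fc = de2$log2fc, fdr = de2$fdr)
  de_double <- data.frame(gene_id = tss_tab$gene_id, expression = expression,
                          log2fc = ded$log2fc, fdr = ded$fdr)

  ## ---- truth -------------------------------------------------------------
  truth <- data.frame(
    gene_id = tss_tab$gene_id, chrom = tss_tab$chrom, pos = tss_tab$pos,
    strand = tss_tab$strand, is_cpg_island = is_cpg, active = active,
    bound = bound, architecture = arch,
    summit_offsets = vapply(summit_off, function(x) paste(x, collapse = ","), ""),
    motif_offsets = vapply(motif_truth, function(x) paste(round(x, 1), collapse = ","), ""),
    ndr_start = ndr_lo, ndr_end = ndr_hi,
    de_single = de_status, de_double = dd_status, redundant = redundant,
    tf2_bound = tss_tab$gene_id %in% tf2_genes,
    stringsAsFactors = FALSE)

  ## ---- write the bundle ---------------------------------------------------
  tss <- point_granges(tss_tab$chrom, tss_tab$pos, strand = tss_tab$strand,
                       gene_id = tss_tab$gene_id)
  islands <- GenomicRanges::GRanges(island_tab$chrom,
                                    IRanges::IRanges(island_tab$start, island_tab$end),
                                    name = island_tab$gene_id,
                                    score = rep(NA_real_, nrow(island_tab)))
  f <- function(x) file.path(dir, x)
  files <- c(
    genome = f("genome.fa"), tss = f("tss.tsv"), cpg_islands = f("cpg_islands.bed"),
    peaks_tf = f(sprintf("peaks_%s.narrowPeak", cfg$factors[1L])),
    peaks_tf2 = f(sprintf("peaks_%s.narrowPeak", cfg$factors[2L])),
    peaks_enhancer = f("peaks_H3K27ac.narrowPeak"),
    peaks_insulator = f("peaks_CTCF.narrowPeak"),
    methyl_calls = f("methyl_calls.tsv"),
    signal_tf = f(sprintf("signal_%s.bedgraph", cfg$factors[1L])),
    signal_tf2 = f(sprintf("signal_%s.bedgraph", cfg$factors[2L])),
    de_single = f(sprintf("de_kd_%s.tsv", cfg$factors[1L])),
    de_single2 = f(sprintf("de_kd_%s.tsv", cfg$factors[2L])),
    de_double = f("de_kd_double.tsv"),
    truth = f("truth.tsv"))
  write_fasta(genome, files["genome"])
  write_tss(tss, files["tss"])
  write_bed(islands, files["cpg_islands"])
  write_narrowpeak(peaks_tf, files["peaks_tf"])
  write_narrowpeak(peaks_tf2, files["peaks_tf2"])
  write_narrowpeak(peaks_enh, files["peaks_enhancer"])
  write_narrowpeak(peaks_ins, files["peaks_insulator"])
  write_methyl_calls(calls, files["methyl_calls"])
  write_bedgraph(signal_tf, files["signal_tf"])
  write_bedgraph(signal_tf2, files["signal_tf2"])
  write_de_table(de_single, files["de_single"])
  write_de_table(de_single2, files["de_single2"])
  write_de_table(de_double, files["de_double"])
  tw <- truth
  tw$pos <- tw$pos - 1L  # file convention: 0-based positions
  tw$ndr_start <- tw$ndr_start - 1L
  data.table::fwrite(tw, files["truth"], sep = "\t", na = "NA")

  peaks <- list(peaks_tf, peaks_tf2, peaks_enh, peaks_ins)
  names(peaks) <- c(cfg$factors, "H3K27ac", "CTCF")
  signal <- list(signal_tf, signal_tf2)
  names(signal) <- cfg$factors
  de <- list(de_single, de_single2, de_double)
  names(de) <- c(cfg$factors, "double")
  list(config = cfg, dir = dir, files = files, truth = truth,
       genome = genome, tss = tss, cpg_islands = islands, peaks = peaks,
       calls = calls, signal = signal, de = de)
}

#' Compare pipeline outputs with planted truth
#'
#' Exact set arithmetic per feature class: precision is the share of reported
#' features matching a planted one, recall the share of planted features
#' recovered. Gene-level classes match by identifier; NDRs match by >= 1 bp
#' interval overlap.
#'
#' @param results A list with any of: `bound_genes` (character),
#'   `down_genes` (character), `ndrs` (`GRanges`).
#' @param truth Truth `data.frame` from [generate_bundle()].
#' @return A `data.frame`: `class`, `precision`, `recall`, `n_true`, `n_called`.
#' @export
truth_compare <- function(results, truth) {
  rows <- list()
  pr <- function(called, true) {
    list(precision = if (length(called) > 0L) mean(called %in% true) else NA_real_,
         recall = if (length(true) > 0L) mean(true %in% called) else NA_real_)
  }
  if (!is.null(results$bound_genes)) {
    unknown <- setdiff(results$bound_genes, truth$gene_id)
    if (length(unknown) > 0L) {
      stopf("truth_compare: unknown gene id(s): %s", paste(head(unknown, 5L), collapse = ", "))
    }
    true <- truth$gene_id[truth$bound]
    x <- pr(results$bound_genes, true)
    rows[[length(rows) + 1L]] <- data.frame(
      class = "binding", precision = x$precision, recall = x$recall,
      n_true = length(true), n_called = length(results$bound_genes))
  }
  if (!is.null(results$down_genes)) {
    unknown <- setdiff(results$down_genes, truth$gene_id)
    if (length(unknown) > 0L) {
      stopf("truth_compare: unknown gene id(s): %s", paste(head(unknown, 5L), collapse = ", "))
    }
    true <- truth$gene_id[truth$de_single == "down"]
    x <- pr(results$down_genes, true)
    rows[[length(rows) + 1L]] <- data.frame(
      class = "de_down", precision = x$precision, recall = x$recall,
      n_true = length(true), n_called = length(results$down_genes))
  }
  if (!is.null(results$ndrs)) {
    planted <- truth[!is.na(truth$ndr_start), ]
    planted_gr <- GenomicRanges::GRanges(planted$chrom,
                                         IRanges::IRanges(planted$ndr_start, planted$ndr_end))
    called <- results$ndrs
    precision <- if (length(called) > 0L) {
      mean(IRanges::overlapsAny(called, planted_gr, ignore.strand = TRUE))
    } else NA_real_
    recall <- if (length(planted_gr) > 0L) {
      mean(IRanges::overlapsAny(planted_gr, called, ignore.strand = TRUE))
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      class = "ndr", precision = precision, recall = recall,
      n_true = length(planted_gr), n_called = length(called))
  }
  do.call(rbind, rows)
}
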