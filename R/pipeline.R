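#' Pipeline configuration
#'
#' Builds the full stage configuration from a named list or a YAML file.
#' Every parameter has a documented default; input paths must exist when
#' [run_all()] is called.
#'
#' @param x Named list of settings, or the path of a YAML file holding one.
#' @return A list of class `pipeline_config` with elements `inputs` (named
#'   file paths), `factors`, and all stage parameters.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    inputs = list(),
    factors = c("ZFX", "ZNF711"),
    half_width = 2000L,
    profile_bin = 20L,
    flat_bin = 1000L,
    metaplot_half_width = 1000L,
    metaplot_bin = 20L,
    motif = "AGGCCTAG",
    n_scrambles = 10L,
    active_threshold = 0,
    fdr_max = 0.05,
    min_abs_fc = 1.5,
    cluster_boundary = 50,
    ndr_min_length = 140L,
    ndr_window = 100L,
    ndr_step = 20L,
    ndr_q_max = 0.05,
    summit_window = c(140, 340),
    seed = 1L)
  cfg <- utils::modifyList(defaults, x)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  path
}

#' Run the full promoter-architecture pipeline
#'
#' Executes every stage against the configured inputs and writes
#' tab-separated result tables, an NDR BED file and a machine-readable JSON
#' manifest (all parameters including defaults, the seed, and input
#' checksums). Rerunning with the same configuration reproduces identical
#' outputs.
#'
#' Required `inputs` entries: `genome`, `tss`, `cpg_islands`, `peaks_tf`,
#' `peaks_tf2`, `peaks_enhancer`, `peaks_insulator`, `methyl_calls`,
#' `signal_tf`, `signal_tf2`, `de_single`, `de_single2`, `de_double`.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced by it).
#' @param out_dir Output directory.
#' @return Invisibly, a named list of all stage results.
#' @export
run_all <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- unlist(config$inputs)
  required <- c("genome", "tss", "cpg_islands", "peaks_tf", "peaks_tf2",
                "peaks_enhancer", "peaks_insulator", "methyl_calls",
                "signal_tf", "signal_tf2", "de_single", "de_single2", "de_double")
  missing_keys <- setdiff(required, names(inputs))
  if (length(missing_keys) > 0L) {
    stopf("pipeline config is missing input(s): %s", paste(missing_keys, collapse = ", "))
  }
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L) {
    stopf("input file(s) not found: %s", paste(absent, collapse = ", "))
  }
  res <- list()
  fct <- config$factors
  out <- function(x) file.path(out_dir, x)

  msg("load", "reading inputs")
  dat <- stage("load", list(
    genome = read_fasta(inputs[["genome"]]),
    tss = read_tss(inputs[["tss"]]),
    islands = read_bed(inputs[["cpg_islands"]]),
    peaks_tf = read_narrowpeak(inputs[["peaks_tf"]]),
    peaks_tf2 = read_narrowpeak(inputs[["peaks_tf2"]]),
    peaks_enh = read_narrowpeak(inputs[["peaks_enhancer"]]),
    peaks_ins = read_narrowpeak(inputs[["peaks_insulator"]]),
    calls = read_methyl_calls(inputs[["methyl_calls"]]),
    signal_tf = read_bedgraph(inputs[["signal_tf"]]),
    signal_tf2 = read_bedgraph(inputs[["signal_tf2"]]),
    de_single = read_de_table(inputs[["de_single"]]),
    de_single2 = read_de_table(inputs[["de_single2"]]),
    de_double = read_de_table(inputs[["de_double"]])))

  msg("annotate", "classifying peaks and promoters")
  res$peak_annotation <- stage("annotate", classify_peaks(
    dat$peaks_tf, dat$tss, dat$peaks_enh, dat$peaks_ins, config$half_width))
  write_tsv(res$peak_annotation, out("peak_annotation.tsv"))
  peaks_by_factor <- list(dat$peaks_tf, dat$peaks_tf2)
  names(peaks_by_factor) <- fct
  res$promoter_status <- stage("annotate", classify_promoters(
    dat$tss, dat$islands, peaks_by_factor, dat$de_single,
    config$active_threshold, config$half_width))
  write_tsv(res$promoter_status, out("promoter_status.tsv"))
  res$peak_overlap <- stage("annotate", peak_set_overlap(dat$peaks_tf2, dat$peaks_tf))

  msg("motif", "positional profile and scrambled controls")
  res$motif_control <- stage("motif-profile", scramble_control(
    dat$tss, dat$genome, config$motif, n = config$n_scrambles,
    seed = config$seed, half_width = config$half_width,
    bin = config$profile_bin, flat_bin = config$flat_bin))
  tp <- res$motif_control$true_profile
  write_tsv(data.frame(offset = tp$mid, count = tp$counts,
                       normalized = tp$normalized), out("motif_profile.tsv"))
  write_tsv(res$motif_control$flatness, out("scramble_flatness.tsv"))
  res$motif_stats <- stage("motif-profile", motif_peak_stats(
    dat$peaks_tf, dat$genome, config$motif))

  msg("summits", "summit-offset architecture")
  res$summit_offsets <- stage("summit-profile", summit_offsets(
    dat$peaks_tf, dat$tss, config$half_width))
  res$summit_profile <- stage("summit-profile", positional_profile(
    res$summit_offsets$offset, anchors = dat$tss,
    half_width = config$half_width, bin = config$profile_bin))
  write_tsv(data.frame(offset = res$summit_profile$mid,
                       count = res$summit_profile$counts),
            out("summit_profile.tsv"))
  single <- stage("summit-profile", select_single_tss_promoters(dat$tss, config$half_width))
  single_bound <- res$summit_offsets[
    res$summit_offsets$gene_id %in% S4Vectors::mcols(single)$gene_id, ]
  res$clusters <- stage("summit-profile", cluster_promoters(
    single_bound, method = "rule", boundary = config$cluster_boundary))
  write_tsv(res$clusters, out("promoter_clusters.tsv"))

  msg("tags", "tag correlation between factors")
  res$tag_correlation <- stage("tags", {
    windows <- promoter_windows(dat$tss, config$half_width)
    count_track <- function(sig) {
      ov <- GenomicRanges::findOverlaps(windows, sig, ignore.strand = TRUE)
      x <- numeric(length(windows))
      if (length(ov) > 0L) {
        pi <- GenomicRanges::pintersect(windows[S4Vectors::queryHits(ov)],
                                        sig[S4Vectors::subjectHits(ov)])
        contrib <- GenomicRanges::width(pi) *
          S4Vectors::mcols(sig)$value[S4Vectors::subjectHits(ov)]
        agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
        x[as.integer(names(agg))] <- agg
      }
      x
    }
    m <- cbind(count_track(dat$signal_tf), count_track(dat$signal_tf2))
    colnames(m) <- fct
    keep <- rowSums(m) > 0
    tag_correlation(m[keep, , drop = FALSE])
  })
  write_tsv(as.data.frame(res$tag_correlation), out("tag_correlation.tsv"))

  msg("de", "binding x differential-expression integration")
  res$expression_contrast <- stage("de-overlap", expression_by_binding(
    res$promoter_status, fct[1L]))
  bound1 <- bound_genes(res$promoter_status, fct[1L])
  de_sets <- stage("de-overlap", select_de_genes(
    dat$de_single, config$fdr_max, config$min_abs_fc))
  res$de_overlap <- stage("de-overlap", de_binding_overlap(
    de_sets$down, de_sets$up, bound1))
  write_tsv(data.frame(
    n_down = res$de_overlap$n_down, n_down_bound = res$de_overlap$n_down_bound,
    pct_down_bound = res$de_overlap$pct_down_bound,
    n_up = res$de_overlap$n_up, n_up_bound = res$de_overlap$n_up_bound,
    pct_up_bound = res$de_overlap$pct_up_bound,
    odds_ratio = res$de_overlap$odds_ratio, p_value = res$de_overlap$p_value),
    out("de_overlap.tsv"))
  de2_sets <- stage("de-overlap", select_de_genes(
    dat$de_single2, config$fdr_max, config$min_abs_fc))
  dd_sets <- stage("de-overlap", select_de_genes(
    dat$de_double, config$fdr_max, config$min_abs_fc))
  res$combinatorial <- stage("de-overlap", combinatorial_kd_overlap(
    setNames(list(de_sets$down, de2_sets$down), fct),
    dd_sets$down, bound1))
  write_tsv(res$combinatorial$membership, out("combinatorial_kd.tsv"))

  msg("ndr", "calling nucleosome-depleted regions")
  res$ndrs <- stage("call-ndrs", call_ndrs(
    dat$calls, min_length = config$ndr_min_length, window = config$ndr_window,
    step = config$ndr_step, q_max = config$ndr_q_max))
  write_bed(GenomicRanges::GRanges(
    GenomicRanges::seqnames(res$ndrs), IRanges::IRanges(
      GenomicRanges::start(res$ndrs), GenomicRanges::end(res$ndrs)),
    name = sprintf("NDR_%04d", seq_along(res$ndrs)),
    score = round(S4Vectors::mcols(res$ndrs)$mean_gch, 4)), out("ndrs.bed"))
  res$peak_ndr <- stage("call-ndrs", {
    so <- res$summit_offsets
    first <- so[!duplicated(so$peak), ]
    idx <- match(res$peak_annotation$peak, first$peak)
    peak_ndr_overlap(dat$peaks_tf, res$ndrs,
                     signed_offsets = first$offset[idx],
                     summit_window = config$summit_window)
  })
  write_tsv(data.frame(fraction = res$peak_ndr$fraction,
                       n_peaks = res$peak_ndr$n_peaks,
                       n_overlapping = res$peak_ndr$n_overlapping),
            out("peak_ndr_overlap.tsv"))

  msg("metaplot", "signal and NOMe metaplots")
  bound_tss <- dat$tss[S4Vectors::mcols(dat$tss)$gene_id %in% bound1]
  res$signal_metaplot <- stage("metaplot", metaplot(
    dat$signal_tf, bound_tss, config$metaplot_half_width, config$metaplot_bin))
  write_tsv(data.frame(offset = res$signal_metaplot$mid,
                       mean_signal = res$signal_metaplot$mean_signal),
            out("metaplot_signal.tsv"))
  res$nome <- stage("metaplot", nome_metaplot(
    dat$calls, bound_tss, config$metaplot_half_width, config$metaplot_bin))
  write_tsv(data.frame(offset = res$nome$GCH$mid,
                       gch = res$nome$GCH$level, hcg = res$nome$HCG$level),
            out("nome_metaplot.tsv"))

  manifest <- list(
    package = "promarch",
    version = as.character(utils::packageVersion("promarch")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "inputs")],
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  msg("done", "all stages complete; outputs in %s", out_dir)
  invisible(res)
}

#' Run the pipeline on a freshly generated synthetic bundle
#'
#' Convenience wrapper: [generate_bundle()] then [run_all()].
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return The [run_all()] result list, plus `bundle`.
#' @export
run_synthetic <- function(sim = sim_config(), out_dir = tempfile("promarch_run"), ...) {
  bundle <- generate_bundle(sim, file.path(out_dir, "inputs"))
  cfg <- pipeline_config(utils::modifyList(list(
    inputs = as.list(bundle$files[c("genome", "tss", "cpg_islands", "peaks_tf",
                                    "peaks_tf2", "peaks_enhancer", "peaks_insulator",
                                    "methyl_calls", "signal_tf", "signal_tf2",
                                    "de_single", "de_single2", "de_double")]),
    factors = sim$factors, motif = sim$motif, seed = sim$seed), list(...)))
  res <- run_all(cfg, file.path(out_dir, "results"))
  res$bundle <- bundle
  invisible(res)
}
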