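# Internal helpers shared across modules.

.datatable.aware <- TRUE

utils::globalVariables(c(
  "dist", "tpos", "idx", "pos", "chrom", "context", "n_methylated", "n_total",
  "offset", "gene_id", "tss_pos", "sign_", "bin", "value", "J", "v", "gid"))

#' @import methods
#' @importFrom stats density kmeans wilcox.test fisher.test p.adjust pbinom
#'   phyper dhyper cor rnorm rbinom rpois rlnorm runif setNames complete.cases
#' @importFrom utils head tail
NULL

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Round half away from zero, the convention used for reported percentages.
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

strand_sign <- function(strand) {
  s <- as.character(strand)
  out <- ifelse(s == "-", -1L, 1L)
  out
}

# Single-base GRanges for a vector of 1-based positions.
point_granges <- function(chrom, pos, strand = "*", ...) {
  if (length(strand) == 1L && length(chrom) != 1L) {
    strand <- rep(strand, length(chrom))
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = strand,
    ...
  )
}

# Per-element plain-decimal formatting (vector format() pads a common width).
fmt_num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), "")
}

msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Warn when chromosomes of `x` are missing from `reference` (silent-mismatch guard).
check_chrom_namespace <- function(x, reference, what = "input") {
  cx <- unique(as.character(GenomicRanges::seqnames(x)))
  cr <- unique(as.character(GenomicRanges::seqnames(reference)))
  missing <- setdiff(cx, cr)
  if (length(missing) > 0L) {
    warning(sprintf(
      "%s chromosomes absent from the TSS annotation: %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(missing)
}
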