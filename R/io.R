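#' File formats and the coordinate convention
#'
#' All readers convert on-disk coordinates to the package-internal convention
#' exactly once: intervals are held as [GenomicRanges::GRanges] (1-based,
#' closed), single-base sites (TSSs, methylation calls) as 1-based positions.
#' On disk everything follows the BED convention (0-based half-open intervals,
#' 0-based single-base positions), which the writers restore verbatim, so
#' read -> write -> read is the identity on every format.
#'
#' @name promarch-io
NULL

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

parse_int <- function(x, line_no, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stopf("%s: line %d: non-integer %s '%s'", path, line_no[bad][1L], what, x[bad][1L])
  }
  v
}

read_lines_nonempty <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  list(lines = lines[keep], line_no = which(keep))
}

#' Read a BED3/BED6 file
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @return A [GenomicRanges::GRanges] in input order with metadata columns
#'   `name` and `score` (both `NA` when absent). File strand "." becomes "*".
#' @export
read_bed <- function(path) {
  lf <- read_lines_nonempty(path)
  if (length(lf$lines) == 0L) return(empty_interval_granges())
  fields <- split_fields(lf$lines)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stopf("%s: line %d: fewer than 3 tab-separated columns", path, lf$line_no[ncol < 3L][1L])
  }
  chrom <- vapply(fields, `[`, "", 1L)
  if (any(!nzchar(chrom))) {
    stopf("%s: line %d: empty chromosome name", path, lf$line_no[!nzchar(chrom)][1L])
  }
  start0 <- parse_int(vapply(fields, `[`, "", 2L), lf$line_no, path, "start")
  end0 <- parse_int(vapply(fields, `[`, "", 3L), lf$line_no, path, "end")
  bad <- end0 <= start0 | start0 < 0L
  if (any(bad)) {
    stopf("%s: line %d: invalid interval [%d, %d)", path, lf$line_no[bad][1L],
          start0[bad][1L], end0[bad][1L])
  }
  name <- ifelse(ncol >= 4L, vapply(fields, function(f) f[4L] %||% NA_character_, ""), NA_character_)
  name[name == "."] <- NA_character_
  score_chr <- ifelse(ncol >= 5L, vapply(fields, function(f) f[5L] %||% NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA_character_, score_chr)))
  strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[6L] %||% ".", ""), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, name = name, score = score)
}

empty_interval_granges <- function() {
  GenomicRanges::GRanges(name = character(0), score = numeric(0))
}

#' Write intervals as BED
#'
#' Records are sorted by chromosome then start; BED6 when any of name, score or
#' strand carries information, BED3 otherwise.
#'
#' @param gr A `GRanges`, optionally with `name` and `score` metadata columns.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  o <- order(chrom, start0, end0)
  name <- S4Vectors::mcols(gr)$name
  score <- S4Vectors::mcols(gr)$score
  strand <- as.character(GenomicRanges::strand(gr))
  bed6 <- (!is.null(name) && any(!is.na(name))) ||
    (!is.null(score) && any(!is.na(score))) || any(strand %in% c("+", "-"))
  if (bed6) {
    name <- if (is.null(name)) rep(NA_character_, length(gr)) else name
    score <- if (is.null(score)) rep(NA_real_, length(gr)) else score
    lines <- paste(chrom[o], start0[o], end0[o],
                   ifelse(is.na(name[o]), ".", name[o]),
                   ifelse(is.na(score[o]), ".", fmt_num(score[o])),
                   ifelse(strand[o] %in% c("+", "-"), strand[o], "."),
                   sep = "\t")
  } else {
    lines <- paste(chrom[o], start0[o], end0[o], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' @param path Path to a 10-column narrowPeak file.
#' @return A `GRanges` with metadata columns `name`, `score`, `signal_value`,
#'   `p_value`, `q_value` and `summit_offset` (0-based offset of the summit
#'   from the peak start; `NA` when column 10 is -1).
#' @export
read_narrowpeak <- function(path) {
  lf <- read_lines_nonempty(path)
  if (length(lf$lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), score = numeric(0), signal_value = numeric(0),
      p_value = numeric(0), q_value = numeric(0), summit_offset = integer(0))
    return(gr)
  }
  fields <- split_fields(lf$lines)
  if (any(lengths(fields) != 10L)) {
    stopf("%s: line %d: narrowPeak requires exactly 10 columns",
          path, lf$line_no[lengths(fields) != 10L][1L])
  }
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start0 <- parse_int(m[, 2L], lf$line_no, path, "start")
  end0 <- parse_int(m[, 3L], lf$line_no, path, "end")
  bad <- end0 <= start0 | start0 < 0L
  if (any(bad)) stopf("%s: line %d: invalid interval", path, lf$line_no[bad][1L])
  summit <- parse_int(m[, 10L], lf$line_no, path, "summit offset")
  width <- end0 - start0
  bad_summit <- summit != -1L & (summit < 0L | summit >= width)
  if (any(bad_summit)) {
    stopf("%s: line %d: summit offset %d outside peak of length %d",
          path, lf$line_no[bad_summit][1L], summit[bad_summit][1L], width[bad_summit][1L])
  }
  strand <- m[, 6L]
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    m[, 1L], IRanges::IRanges(start0 + 1L, end0), strand = strand,
    name = m[, 4L], score = suppressWarnings(as.numeric(m[, 5L])),
    signal_value = suppressWarnings(as.numeric(m[, 7L])),
    p_value = suppressWarnings(as.numeric(m[, 8L])),
    q_value = suppressWarnings(as.numeric(m[, 9L])),
    summit_offset = ifelse(summit == -1L, NA_integer_, summit))
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param gr A `GRanges` with (optionally) the metadata columns produced by
#'   [read_narrowpeak()]. A missing/`NA` `summit_offset` is written as -1.
#' @param path Output path.
#' @export
write_narrowpeak <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  o <- order(chrom, start0, end0)
  mc <- S4Vectors::mcols(gr)
  col <- function(nm, default) if (!is.null(mc[[nm]])) mc[[nm]] else rep(default, length(gr))
  name <- col("name", NA_character_)
  score <- col("score", 0)
  strand <- as.character(GenomicRanges::strand(gr))
  sv <- col("signal_value", 0)
  pv <- col("p_value", -1)
  qv <- col("q_value", -1)
  so <- col("summit_offset", NA_integer_)
  fmt <- function(x) ifelse(is.na(x), "0", fmt_num(x))
  lines <- paste(chrom[o], start0[o], end0[o],
                 ifelse(is.na(name[o]), ".", name[o]),
                 fmt(score[o]),
                 ifelse(strand[o] %in% c("+", "-"), strand[o], "."),
                 fmt(sv[o]), fmt(pv[o]), fmt(qv[o]),
                 ifelse(is.na(so[o]), "-1", as.character(so[o])),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Absolute summit positions of peaks
#'
#' Peaks without a recorded summit fall back to the interval midpoint (a
#' message notes how many).
#'
#' @param peaks A `GRanges` with a `summit_offset` metadata column.
#' @return Integer vector of 1-based summit positions.
#' @export
summit_positions <- function(peaks) {
  so <- S4Vectors::mcols(peaks)$summit_offset
  if (is.null(so)) so <- rep(NA_integer_, length(peaks))
  mid <- GenomicRanges::start(peaks) +
    (GenomicRanges::width(peaks) - 1L) %/% 2L
  n_absent <- sum(is.na(so))
  if (n_absent > 0L) msg("summits", "%d peak(s) without summit: using interval midpoint", n_absent)
  ifelse(is.na(so), mid, GenomicRanges::start(peaks) + as.integer(so))
}

#' Read a TSS table
#'
#' Format: `chrom<TAB>pos<TAB>strand<TAB>gene_id`, positions 0-based, strand
#' `+` or `-`. A header line starting with `#` is skipped.
#'
#' @param path Path to the table.
#' @return A width-1 `GRanges` with a `gene_id` metadata column.
#' @export
read_tss <- function(path) {
  lf <- read_lines_nonempty(path)
  keep <- !startsWith(lf$lines, "#")
  lines <- lf$lines[keep]; line_no <- lf$line_no[keep]
  if (length(lines) == 0L) return(point_granges(character(0), integer(0), gene_id = character(0)))
  fields <- split_fields(lines)
  if (any(lengths(fields) < 4L)) {
    stopf("%s: line %d: TSS table needs 4 columns (chrom, pos, strand, gene_id)",
          path, line_no[lengths(fields) < 4L][1L])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  pos0 <- parse_int(m[, 2L], line_no, path, "position")
  bad <- !m[, 3L] %in% c("+", "-")
  if (any(bad)) stopf("%s: line %d: TSS strand must be '+' or '-', got '%s'",
                      path, line_no[bad][1L], m[bad, 3L][1L])
  point_granges(m[, 1L], pos0 + 1L, strand = m[, 3L], gene_id = m[, 4L])
}

#' @rdname read_tss
#' @param tss A TSS `GRanges` as returned by [read_tss()].
#' @export
write_tss <- function(tss, path) {
  chrom <- as.character(GenomicRanges::seqnames(tss))
  pos0 <- GenomicRanges::start(tss) - 1L
  o <- order(chrom, pos0)
  lines <- paste(chrom[o], pos0[o], as.character(GenomicRanges::strand(tss))[o],
                 S4Vectors::mcols(tss)$gene_id[o], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cytosine methylation call table
#'
#' Format (tab-separated, optional `#`-prefixed header):
#' `chrom, pos (0-based), strand, context (HCG|GCH), n_methylated, n_total`.
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `n_methylated`, `n_total`.
#' @export
read_methyl_calls <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) == 1L && startsWith(first, "#")) 1L else 0L
  dt <- data.table::fread(
    path, sep = "\t", header = FALSE, skip = skip,
    col.names = c("chrom", "pos", "strand", "context", "n_methylated", "n_total"),
    colClasses = list(character = c(1, 3, 4), integer = c(2, 5, 6)))
  off <- skip  # file line = row index + header offset
  bad_ctx <- !dt$context %in% c("HCG", "GCH")
  if (any(bad_ctx)) {
    stopf("%s: line %d: unknown methylation context '%s' (expected HCG or GCH)",
          path, which(bad_ctx)[1L] + off, dt$context[bad_ctx][1L])
  }
  bad_n <- dt$n_total < 1L | dt$n_methylated < 0L | dt$n_methylated > dt$n_total
  if (any(bad_n)) {
    stopf("%s: line %d: invalid counts n_methylated=%d n_total=%d",
          path, which(bad_n)[1L] + off, dt$n_methylated[bad_n][1L], dt$n_total[bad_n][1L])
  }
  dt$pos <- dt$pos + 1L
  data.table::setDF(dt)
  dt
}

#' @rdname read_methyl_calls
#' @param calls Methylation-call `data.frame` as returned by [read_methyl_calls()].
#' @export
write_methyl_calls <- function(calls, path) {
  dt <- data.table::as.data.table(calls)
  dt$pos <- dt$pos - 1L
  data.table::setorderv(dt, c("chrom", "pos", "context"))
  writeLines("#chrom\tpos\tstrand\tcontext\tn_methylated\tn_total", path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Format (tab-separated, optional header): `gene_id, expression, log2fc, fdr`.
#'
#' @param path Path to the table.
#' @return A `data.frame` with those four columns.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) == 1L &&
              (startsWith(first, "#") || startsWith(first, "gene_id"))) 1L else 0L
  dt <- data.table::fread(
    path, sep = "\t", header = FALSE, skip = skip,
    col.names = c("gene_id", "expression", "log2fc", "fdr"),
    colClasses = list(character = 1, numeric = 2:4))
  dup <- unique(dt$gene_id[duplicated(dt$gene_id)])
  if (length(dup) > 0L) {
    stopf("%s: duplicate gene_id(s): %s", path,
          paste(head(dup, 10L), collapse = ", "))
  }
  bad <- !is.na(dt$fdr) & (dt$fdr < 0 | dt$fdr > 1)
  if (any(bad)) stopf("%s: line %d: fdr outside [0, 1]", path, which(bad)[1L] + skip)
  if (any(!is.na(dt$expression) & dt$expression < 0)) {
    stopf("%s: negative expression value", path)
  }
  data.table::setDF(dt)
  dt
}

#' @rdname read_de_table
#' @param de DE `data.frame` as returned by [read_de_table()].
#' @export
write_de_table <- function(de, path) {
  dt <- data.table::as.data.table(de)
  data.table::setorderv(dt, "gene_id")
  writeLines("gene_id\texpression\tlog2fc\tfdr", path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph (`chrom, start, end, value`).
#' @return A `GRanges` with a `value` metadata column.
#' @export
read_bedgraph <- function(path) {
  lf <- read_lines_nonempty(path)
  keep <- !startsWith(lf$lines, "track") & !startsWith(lf$lines, "#")
  lines <- lf$lines[keep]; line_no <- lf$line_no[keep]
  if (length(lines) == 0L) return(GenomicRanges::GRanges(value = numeric(0)))
  fields <- split_fields(lines)
  if (any(lengths(fields) < 4L)) {
    stopf("%s: line %d: bedGraph needs 4 columns", path, line_no[lengths(fields) < 4L][1L])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  start0 <- parse_int(m[, 2L], line_no, path, "start")
  end0 <- parse_int(m[, 3L], line_no, path, "end")
  if (any(end0 <= start0)) stopf("%s: line %d: end <= start", path, line_no[end0 <= start0][1L])
  value <- suppressWarnings(as.numeric(m[, 4L]))
  if (any(is.na(value))) stopf("%s: line %d: non-numeric value", path, line_no[is.na(value)][1L])
  GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start0 + 1L, end0), value = value)
}

#' @rdname read_bedgraph
#' @param gr Signal `GRanges` with a `value` column.
#' @export
write_bedgraph <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  o <- order(chrom, start0)
  lines <- paste(chrom[o], start0[o], GenomicRanges::end(gr)[o],
                 fmt_num(S4Vectors::mcols(gr)$value[o]),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' bases are upper-cased on read.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' @rdname read_fasta
#' @param seqs A `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
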