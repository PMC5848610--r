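#' Expression of bound versus unbound active promoters
#'
#' Compares normalized expression between genes whose active promoters are
#' bound by a factor and genes whose active promoters are not, with a
#' two-sided rank-sum (Wilcoxon) test.
#'
#' @param promoter_status Output of [classify_promoters()].
#' @param factor Factor label (selects the `bound_<factor>` column).
#' @return A list: `bound`, `unbound` (expression vectors), `median_bound`,
#'   `median_unbound`, `p_value`, `n_bound`, `n_unbound`.
#' @export
expression_by_binding <- function(promoter_status, factor) {
  col <- paste0("bound_", factor)
  if (is.null(promoter_status[[col]])) stopf("no binding column for factor '%s'", factor)
  active <- promoter_status[!is.na(promoter_status$is_active) & promoter_status$is_active, ]
  x <- active$expression[active[[col]]]
  y <- active$expression[!active[[col]]]
  if (length(x) < 2L || length(y) < 2L) {
    stopf("expression_by_binding: need >= 2 active genes in each group (bound %d, unbound %d)",
          length(x), length(y))
  }
  p <- suppressWarnings(wilcox.test(x, y)$p.value)
  list(bound = x, unbound = y,
       median_bound = stats::median(x), median_unbound = stats::median(y),
       p_value = p, n_bound = length(x), n_unbound = length(y))
}

#' Select differentially expressed genes
#'
#' Strict thresholds: `fdr < fdr_max` and `|fold change| > min_abs_fc`, i.e.
#' `log2fc < -log2(min_abs_fc)` for down- and `log2fc > log2(min_abs_fc)`
#' for up-regulated genes.
#'
#' @param de DE `data.frame` (`gene_id`, `expression`, `log2fc`, `fdr`).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param min_abs_fc Minimum absolute fold change (default 1.5, linear scale).
#' @return A list with character vectors `down` and `up`.
#' @export
select_de_genes <- function(de, fdr_max = 0.05, min_abs_fc = 1.5) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(de)))
  lfc <- log2(min_abs_fc)
  ok <- !is.na(de$fdr) & !is.na(de$log2fc) & de$fdr < fdr_max
  list(down = de$gene_id[ok & de$log2fc < -lfc],
       up = de$gene_id[ok & de$log2fc > lfc])
}

#' Binding overlap of down- versus up-regulated genes
#'
#' Builds the 2x2 table (down, up) x (bound, unbound), reports the percentage
#' of each DE class with bound promoters (one decimal, half away from zero),
#' the sample odds ratio `(a*d)/(b*c)` and exact-test p-values.
#'
#' @param down,up Character vectors of down-/up-regulated gene ids.
#' @param bound_gene_set Character vector of genes with bound promoters.
#' @param alternative `"two.sided"` (Fisher's exact, default) or `"greater"`
#'   (one-sided hypergeometric: bound enriched among down-regulated genes).
#' @return A list of class `de_overlap`: `n_down`, `n_up`, `n_down_bound`,
#'   `n_up_bound`, `pct_down_bound`, `pct_up_bound`, `odds_ratio`, `p_value`,
#'   and `p_mid` (one-sided hypergeometric mid-p, the calibrated variant of
#'   the exact p-value; see the methods vignette).
#' @export
de_binding_overlap <- function(down, up, bound_gene_set,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n_down <- length(unique(down)); n_up <- length(unique(up))
  if (n_down == 0L || n_up == 0L) {
    stopf("de_binding_overlap: empty DE class (down %d, up %d)", n_down, n_up)
  }
  bound_gene_set <- unique(bound_gene_set)
  a <- sum(unique(down) %in% bound_gene_set)  # down, bound
  b <- n_down - a                             # down, unbound
  c_ <- sum(unique(up) %in% bound_gene_set)   # up, bound
  d <- n_up - c_                              # up, unbound
  or <- if (a * d == 0) {
    if (b * c_ == 0) 0 else 0
  } else if (b * c_ == 0) Inf else (a * d) / (b * c_)
  tb <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE)
  p <- fisher.test(tb, alternative = alternative)$p.value
  # one-sided hypergeometric mid-p: P(X > a) + P(X = a)/2 with X the number of
  # bound genes among the down-regulated class
  p_mid <- phyper(a - 1, a + c_, b + d, n_down, lower.tail = FALSE) -
    0.5 * dhyper(a, a + c_, b + d, n_down)
  structure(list(
    n_down = n_down, n_up = n_up, n_down_bound = a, n_up_bound = c_,
    pct_down_bound = round_half_away(100 * a / n_down, 1L),
    pct_up_bound = round_half_away(100 * c_ / n_up, 1L),
    odds_ratio = or, p_value = p, p_mid = p_mid,
    table = tb), class = "de_overlap")
}

#' @export
print.de_overlap <- function(x, ...) {
  cat(sprintf("down-regulated: %d/%d bound (%.1f%%); up-regulated: %d/%d bound (%.1f%%)\n",
              x$n_down_bound, x$n_down, x$pct_down_bound,
              x$n_up_bound, x$n_up, x$pct_up_bound))
  cat(sprintf("odds ratio %.3g, exact p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Additional bound-down genes in a combinatorial knockdown
#'
#' Genes that are down-regulated with bound promoters in the double knockdown
#' but in neither single knockdown -- the redundancy signature.
#'
#' @param single_down List of character vectors: down-regulated genes in each
#'   single knockdown.
#' @param double_down Character vector: down-regulated genes in the double
#'   knockdown.
#' @param bound_gene_set Character vector of genes with bound promoters.
#' @return A list: `additional` (gene ids), `n_additional`, and `membership`
#'   (`data.frame` of every bound-down-anywhere gene with logical columns per
#'   knockdown).
#' @export
combinatorial_kd_overlap <- function(single_down, double_down, bound_gene_set) {
  stopifnot(is.list(single_down))
  bound_gene_set <- unique(bound_gene_set)
  singles_bd <- lapply(single_down, function(g) intersect(unique(g), bound_gene_set))
  double_bd <- intersect(unique(double_down), bound_gene_set)
  any_single <- unique(unlist(singles_bd))
  additional <- setdiff(double_bd, any_single)
  all_genes <- sort(unique(c(any_single, double_bd)))
  membership <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  nm <- names(single_down) %||% paste0("single", seq_along(single_down))
  for (i in seq_along(singles_bd)) {
    membership[[paste0("down_", nm[i])]] <- all_genes %in% singles_bd[[i]]
  }
  membership$down_double <- all_genes %in% double_bd
  list(additional = additional, n_additional = length(additional),
       membership = membership)
}
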