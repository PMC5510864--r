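#' Carrier vs non-carrier expression test (retroduplication eQTL scan)
#'
#' Within one population, each parent gene's expression is compared between
#' carriers (individuals with a novel retroduplication of that gene) and
#' non-carriers by a two-sided Wilcoxon rank-sum test; p-values are adjusted
#' across genes by Benjamini-Hochberg. The exact null distribution is used
#' when both groups have at most `exact_max` members and the data are free
#' of ties; otherwise the normal approximation with tie correction applies.
#' Genes without both a carrier and a non-carrier, or with zero expression
#' variance, are skipped (recorded in the `skipped` attribute).
#'
#' @param expression Numeric matrix genes x individuals for one population.
#' @param carriers Logical/0-1 matrix of the same shape: carrier status of
#'   each individual for each (parent) gene. Genes absent from `carriers`
#'   are not tested.
#' @param exact_max Largest group size for exact enumeration (default 10).
#' @return `data.frame`: `gene_id`, `statistic` (rank-sum W), `p`,
#'   `p_adjusted`; attribute `skipped` lists untested genes with reasons.
#' @export
eqtl_test <- function(expression, carriers, exact_max = 10L) {
  genes <- intersect(rownames(expression), rownames(carriers))
  rows <- list(); skipped <- list()
  for (g in genes) {
    x <- as.numeric(expression[g, ])
    cs <- as.logical(carriers[g, colnames(expression)])
    if (!any(cs) || all(cs)) {
      skipped[[g]] <- "needs both carriers and non-carriers"; next
    }
    if (stats::var(x) == 0) {
      skipped[[g]] <- "zero expression variance"; next
    }
    a <- x[cs]; b <- x[!cs]
    use_exact <- max(length(a), length(b)) <= exact_max &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                              correct = !use_exact))
    rows[[g]] <- data.frame(gene_id = g, statistic = unname(wt$statistic),
                            p = wt$p.value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), statistic = numeric(), p = numeric())
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Fisher's combined probability (omnibus) test
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p))`, compared to
#' a chi-square distribution with 2k degrees of freedom. Independence is
#' assumed, as in the per-gene tests it aggregates; this is a documented
#' limitation rather than a corrected-for feature.
#'
#' @param p_values Vector of (unadjusted) p-values.
#' @return Combined p-value.
#' @export
omnibus_fisher <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) return(NA_real_)
  x2 <- -2 * sum(log(pmax(p_values, .Machine$double.xmin)))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Paired signed-rank test on per-gene carrier/non-carrier medians
#'
#' For each gene, the median expression of carriers is paired with the
#' median of non-carriers; the two-sided Wilcoxon signed-rank test is
#' applied across genes.
#'
#' @param median_carriers,median_noncarriers Per-gene medians (same order).
#' @return p-value of the two-sided signed-rank test (1 when every
#'   difference is zero).
#' @export
paired_signed_rank <- function(median_carriers, median_noncarriers) {
  d <- median_carriers - median_noncarriers
  if (all(d == 0)) return(1)
  wt <- suppressWarnings(stats::wilcox.test(median_carriers,
                                            median_noncarriers,
                                            paired = TRUE))
  wt$p.value
}

#' Are parent genes highly expressed among all genes?
#'
#' Every gene is summarized by its median expression over individuals. For
#' each parent gene, the one-tailed empirical p-value is the fraction of all
#' genes (parent included, numerator and denominator both counting it) whose
#' median is at least the parent's:
#' `p = #\{median_g >= median_parent\} / (G + 1)` over `G` genes plus the
#' implicit tie with itself — the global maximum among G = 999 genes scores
#' 1/1000. The per-parent p-values are combined with Fisher's method.
#'
#' @param parent_genes Character vector of parent gene ids.
#' @param expression Numeric matrix, all measured genes x individuals.
#' @return List with `per_gene` (`data.frame`: `gene_id`, `median`,
#'   `p_empirical`) and `omnibus_p`.
#' @export
expression_rank_test <- function(parent_genes, expression) {
  med <- apply(expression, 1L, stats::median)
  G <- length(med)
  parent_genes <- intersect(parent_genes, names(med))
  p <- vapply(parent_genes, function(g) sum(med >= med[g]) / (G + 1),
              numeric(1))
  list(per_gene = data.frame(gene_id = parent_genes,
                             median = unname(med[parent_genes]),
                             p_empirical = unname(p),
                             stringsAsFactors = FALSE),
       omnibus_p = omnibus_fisher(p))
}

#' Run the expression-association battery for one population
#'
#' Convenience wrapper: rank-sum eQTL scan, Fisher omnibus on its unadjusted
#' p-values, the paired signed-rank re-test on group medians, and the
#' expression-rank analysis of parent genes against all genes.
#'
#' @inheritParams eqtl_test
#' @param all_expression Optional full expression matrix (all measured
#'   genes) for the rank analysis; defaults to `expression`.
#' @return List with `eqtl`, `omnibus_p`, `signed_rank_p`, `rank_test`.
#' @export
association_battery <- function(expression, carriers, all_expression = NULL) {
  eq <- eqtl_test(expression, carriers)
  genes <- eq$gene_id
  med_c <- med_n <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    cs <- as.logical(carriers[g, colnames(expression)])
    med_c[i] <- stats::median(expression[g, cs])
    med_n[i] <- stats::median(expression[g, !cs])
  }
  list(eqtl = eq,
       omnibus_p = omnibus_fisher(eq$p),
       signed_rank_p = if (length(genes)) paired_signed_rank(med_c, med_n) else NA_real_,
       rank_test = expression_rank_test(genes,
                                        all_expression %||% expression))
}
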