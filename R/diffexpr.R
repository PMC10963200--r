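#' Two-group differential expression with logFC and FDR cutoffs
#'
#' Per gene: logFC is the difference of group means on the log2 scale
#' (`group1` minus `group2`), the p-value comes from Welch's t-test, and
#' q-values are Benjamini-Hochberg adjusted over all tested genes. A gene is
#' significant when `|logFC| >= logfc_cutoff` and `q < q_cutoff` (defaults 2
#' and 0.05). Genes with zero variance in both groups are assigned p = 1 and
#' excluded when the group means agree (no evidence), and p = 0 when they
#' differ (a perfect separator, the zero-noise limit).
#'
#' @param expr genes x samples log2 expression matrix.
#' @param groups character/factor of group labels, one per sample (column).
#' @param group1,group2 the two labels to contrast; default the first two
#'   levels in `sort(unique(groups))`. logFC is `group1 - group2`.
#' @param logfc_cutoff minimum absolute log2 fold change (inclusive).
#' @param q_cutoff strict upper bound on the BH q-value.
#' @return An object of class `deg_result`: list with `table` (all tested
#'   genes: `gene_id`, `logfc`, `p`, `q`, `direction`), `significant` (the
#'   filtered table, ordered by decreasing `|logfc|`, gene id as tiebreak),
#'   `all_tested`, `logfc_cutoff`, `q_cutoff`.
#' @export
run_deg <- function(expr, groups, group1 = NULL, group2 = NULL,
                    logfc_cutoff = 2, q_cutoff = 0.05) {
  expr <- as_expression_matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) {
    stop("one group label per sample column required")
  }
  levs <- sort(unique(groups))
  if (is.null(group1)) group1 <- levs[1]
  if (is.null(group2)) group2 <- setdiff(levs, group1)[1]
  i1 <- which(groups == group1)
  i2 <- which(groups == group2)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("insufficient replication: each group needs at least 2 samples")
  }

  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  logfc <- m1 - m2

  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, logfc / sqrt(se2), sign(logfc) * Inf)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  # zero within-group variance: no evidence when the means agree (p = 1,
  # excluded), a perfect separator when they differ (p = 0)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(logfc != 0, 0, 1))
  q <- bh_adjust(p)

  tab <- data.frame(
    gene_id = rownames(expr), logfc = logfc, p = p, q = q,
    direction = ifelse(logfc > 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  flat <- se2 == 0 & logfc == 0
  sig <- tab[abs(tab$logfc) >= logfc_cutoff & tab$q < q_cutoff & !flat, ,
             drop = FALSE]
  sig <- sig[order(-abs(sig$logfc), sig$gene_id), , drop = FALSE]
  rownames(sig) <- NULL

  structure(list(table = tab, significant = sig, all_tested = nrow(tab),
                 group1 = group1, group2 = group2,
                 logfc_cutoff = logfc_cutoff, q_cutoff = q_cutoff),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("Differential expression:", x$group1, "vs", x$group2, "\n")
  cat(sprintf("  %d genes tested, %d significant (|logFC| >= %g, q < %g)\n",
              x$all_tested, nrow(x$significant), x$logfc_cutoff, x$q_cutoff))
  cat(sprintf("  %d up, %d down\n", sum(x$significant$direction == "up"),
              sum(x$significant$direction == "down")))
  invisible(x)
}

#' Intersect significant DEGs with a signature gene set
#'
#' The differentially expressed signature genes (DEMISGs) are the significant
#' genes that also belong to the named signature set. An empty intersection
#' warns rather than errors.
#'
#' @param deg a [run_deg()] result.
#' @param signature character vector of signature gene ids.
#' @return Sorted character vector of overlapping gene ids.
#' @export
intersect_signature <- function(deg, signature) {
  stopifnot(inherits(deg, "deg_result"))
  out <- sort(intersect(deg$significant$gene_id, signature))
  if (length(out) == 0) {
    warning("empty intersection between significant genes and signature")
  }
  out
}
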