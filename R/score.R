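#' tSNE embedding of samples on the signature genes
#'
#' Embeds samples in two dimensions with tSNE (exact gradient, `theta = 0`,
#' which is both deterministic given the seed and accurate at the sample
#' sizes this pipeline targets). Genes are z-scored first, matching the
#' consensus-clustering preprocessing.
#'
#' @param expr genes x samples matrix, typically restricted to the DEMISGs.
#' @param perplexity tSNE perplexity; requires `n > 3 * perplexity`.
#' @param seed integer seed (the embedding, and hence the response score, is
#'   seed-dependent by construction, so a pinned seed is mandatory).
#' @param scale_genes z-score genes first (default TRUE).
#' @return data.frame with `sample_id`, `coord1`, `coord2`.
#' @export
tsne_embed <- function(expr, perplexity = 30, seed = 1L, scale_genes = TRUE) {
  expr <- as_expression_matrix(expr)
  n <- ncol(expr)
  if (n <= 3 * perplexity) {
    stop("perplexity too large: need n > 3 * perplexity (n = ", n,
         ", bound = ", 3 * perplexity, ")")
  }
  x <- expr
  if (scale_genes) {
    sd <- apply(x, 1, stats::sd)
    sd[sd == 0] <- 1
    x <- (x - rowMeans(x)) / sd
  }
  emb <- with_seed(seed, {
    Rtsne::Rtsne(t(x), dims = 2, perplexity = perplexity, theta = 0,
                 check_duplicates = FALSE, pca = TRUE, num_threads = 1)$Y
  })
  data.frame(sample_id = colnames(expr), coord1 = emb[, 1], coord2 = emb[, 2],
             stringsAsFactors = FALSE)
}

#' Per-sample response score from a 2-D embedding
#'
#' The score is the raw coordinate sum `coord1 + coord2`, with no rescaling.
#' Summing embedding coordinates is rotation-sensitive and carries no
#' absolute scale; the score is meaningful only relative to other samples in
#' the same embedding under the same seed.
#'
#' @param coords data.frame with `sample_id`, `coord1`, `coord2` (as returned
#'   by [tsne_embed()]).
#' @return the input with a `score` column appended.
#' @export
response_score <- function(coords) {
  stopifnot(all(c("sample_id", "coord1", "coord2") %in% names(coords)))
  if (!all(is.finite(coords$coord1)) || !all(is.finite(coords$coord2))) {
    stop("non-finite embedding coordinates")
  }
  coords$score <- coords$coord1 + coords$coord2
  coords
}

#' Compare response scores between two subtypes
#'
#' @param scores numeric score per sample.
#' @param subtype "M1"/"M2" label per sample, same order.
#' @return list with `mean_M1`, `mean_M2`, and the Welch-t `p` value.
#' @export
compare_scores <- function(scores, subtype) {
  if (length(scores) != length(subtype)) stop("length mismatch")
  s1 <- scores[subtype == "M1"]
  s2 <- scores[subtype == "M2"]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each subtype needs at least 2 samples")
  }
  wt <- welch_t(s2, s1)
  list(mean_M1 = mean(s1), mean_M2 = mean(s2), p = wt$p)
}
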