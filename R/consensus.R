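#' Configuration for Monti-style consensus clustering
#'
#' Defaults reproduce the reference call used for subtype discovery:
#' `max_k = 6`, `reps = 1000`, `p_item = 0.8`, `p_feature = 1`, k-means inner
#' clustering with Euclidean distance.
#'
#' @param max_k largest number of clusters evaluated (k runs 2..`max_k`).
#' @param reps number of resampling repetitions.
#' @param p_item fraction of samples drawn (without replacement) per rep.
#' @param p_feature fraction of gene features drawn per rep.
#' @param seed integer seed; per-rep streams are derived from it.
#' @return A validated `consensus_config` list.
#' @export
consensus_config <- function(max_k = 6L, reps = 1000L, p_item = 0.8,
                             p_feature = 1, seed = 1L) {
  if (max_k < 2) stop("max_k must be >= 2")
  if (reps < 1) stop("reps must be positive")
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]")
  if (p_feature <= 0 || p_feature > 1) stop("p_feature must be in (0, 1]")
  structure(list(max_k = as.integer(max_k), reps = as.integer(reps),
                 p_item = p_item, p_feature = p_feature,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Resampling-based consensus clustering of samples
#'
#' For each repetition a fraction `p_item` of samples (and `p_feature` of
#' gene features, when below 1) is drawn without replacement and partitioned
#' by k-means (10 random restarts, 300 iteration cap). The consensus matrix
#' entry for a sample pair is the number of times the pair co-clustered
#' divided by the number of times it was co-sampled. Final per-k assignments
#' come from average-linkage hierarchical clustering of `1 - consensus`.
#' Genes are z-scored before clustering (constant genes contribute 0).
#'
#' Subsamples with fewer distinct points than k are redrawn (counted); more
#' than 10% redraws for any k is an error. Pairs never co-sampled (possible
#' at low `reps`) get consensus 0 and raise the `never_cosampled` flag.
#'
#' @param expr genes x samples matrix, typically restricted to the DEMISG
#'   genes.
#' @param cfg a [consensus_config()].
#' @param scale_genes z-score each gene before clustering (default TRUE).
#' @param store_partitions keep every repetition's subsample and labels
#'   (memory-heavy; meant for audits at small `reps`).
#' @return An object of class `consensus_run`: per k (named "2".."max_k")
#'   a list with `consensus` (n x n symmetric matrix, diagonal 1),
#'   `assignments` (integer cluster per sample), `cluster_consensus`
#'   (per-cluster mean within-cluster consensus), `area` (area under the
#'   consensus CDF), `delta_area`, `redraws`, plus top-level `samples`,
#'   `never_cosampled`, and (optionally) `partitions`.
#' @export
consensus_cluster <- function(expr, cfg = consensus_config(),
                              scale_genes = TRUE, store_partitions = FALSE) {
  expr <- as_expression_matrix(expr)
  n <- ncol(expr)
  if (n < cfg$max_k + 1) stop("need at least max_k + 1 samples")
  x <- expr
  if (scale_genes) {
    mu <- rowMeans(x)
    sd <- apply(x, 1, stats::sd)
    sd[sd == 0] <- 1
    x <- (x - mu) / sd
  }
  s <- t(x) # samples in rows, gene features in columns
  ks <- 2:cfg$max_k
  n_item <- ceiling(cfg$p_item * n)
  n_feat <- ceiling(cfg$p_feature * nrow(x))

  co <- lapply(ks, function(k) matrix(0, n, n))
  cnt <- lapply(ks, function(k) matrix(0, n, n))
  names(co) <- names(cnt) <- as.character(ks)
  redraws <- stats::setNames(integer(length(ks)), as.character(ks))
  parts <- if (store_partitions) {
    stats::setNames(lapply(ks, function(k) vector("list", cfg$reps)),
                    as.character(ks))
  } else NULL
  max_redraw <- ceiling(0.1 * cfg$reps)

  for (r in seq_len(cfg$reps)) {
    set.seed(sub_seed(cfg$seed, r))
    items <- sort(sample.int(n, n_item))
    feats <- if (cfg$p_feature < 1) {
      sort(sample.int(nrow(x), n_feat))
    } else seq_len(nrow(x))
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      it <- items
      sub <- s[it, feats, drop = FALSE]
      tries <- 0L
      labels <- NULL
      repeat {
        if (sum(!duplicated(sub)) >= k) {
          labels <- tryCatch(
            stats::kmeans(sub, centers = k, nstart = 10,
                          iter.max = 300)$cluster,
            error = function(e) NULL)
        }
        if (!is.null(labels)) break
        redraws[ki] <- redraws[ki] + 1L
        tries <- tries + 1L
        if (redraws[ki] > max_redraw) {
          stop("consensus clustering: more than 10% degenerate subsamples ",
               "at k = ", k)
        }
        it <- sort(sample.int(n, n_item))
        sub <- s[it, feats, drop = FALSE]
      }
      same <- outer(labels, labels, "==") * 1
      co[[ki]][it, it] <- co[[ki]][it, it] + same
      cnt[[ki]][it, it] <- cnt[[ki]][it, it] + 1
      if (store_partitions) parts[[ki]][[r]] <- list(items = it, labels = labels)
    }
  }

  never <- FALSE
  per_k <- vector("list", length(ks))
  names(per_k) <- as.character(ks)
  areas <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    m <- co[[ki]] / ifelse(cnt[[ki]] > 0, cnt[[ki]], 1)
    off <- cnt[[ki]][upper.tri(cnt[[ki]])]
    if (any(off == 0)) never <- TRUE
    diag(m) <- 1
    dimnames(m) <- list(colnames(expr), colnames(expr))
    hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
    assign <- stats::cutree(hc, k = k)
    cc <- vapply(seq_len(k), function(c) {
      idx <- which(assign == c)
      if (length(idx) < 2) return(NA_real_)
      sub <- m[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    u <- sort(m[upper.tri(m)])
    areas[ki] <- cdf_area(u)
    per_k[[ki]] <- list(consensus = m, assignments = assign,
                        cluster_consensus = cc, area = areas[ki],
                        cdf_values = u, redraws = redraws[ki])
  }
  for (ki in seq_along(ks)) {
    per_k[[ki]]$delta_area <- if (ki == 1) areas[1] else {
      (areas[ki] - areas[ki - 1]) / areas[ki - 1]
    }
  }
  structure(list(k = per_k, samples = colnames(expr), config = cfg,
                 never_cosampled = never, partitions = parts),
            class = "consensus_run")
}

# Area under the empirical CDF of consensus values on [0, 1]
# (the standard diagnostic for choosing k).
cdf_area <- function(u) {
  if (length(u) == 0) return(0)
  pts <- sort(unique(c(0, u, 1)))
  cdf <- vapply(pts, function(g) mean(u <= g), numeric(1))
  sum(diff(pts) * cdf[-length(cdf)]) # right-continuous step integral on [0,1]
}

#' Choose the number of clusters from consensus diagnostics
#'
#' Formalizes the usual visual rule, combining the CDF delta-area plot with
#' cluster stability: a value of k qualifies when its relative change in CDF
#' area exceeds `delta_threshold` (for k = 2 the change is the area itself)
#' AND its least stable cluster keeps a within-cluster consensus of at least
#' `consensus_floor` (a singleton cluster fails this test). The selected k is
#' the largest qualifying k. Splitting a true cluster always produces at
#' least one unstable cluster, so the floor is what stops k from creeping
#' past the real structure; the delta-area threshold stops it where the CDF
#' gain is negligible. If no k qualifies (structureless data: near-uniform
#' CDFs, low consensus everywhere), the k with the highest mean
#' cluster-consensus is returned flagged low-confidence. The full per-k
#' report is always returned so a human can override the automated choice.
#'
#' @param run a [consensus_cluster()] result.
#' @param delta_threshold relative delta-area cutoff (default 0.1).
#' @param consensus_floor minimum per-cluster consensus a qualifying k must
#'   keep in every cluster (default 0.9, calibrated on planted block
#'   structures; see the methods vignette).
#' @return list with `k_star`, `low_confidence`, and `report` (data.frame of
#'   k, area, delta_area, min/mean cluster consensus, qualifies).
#' @export
select_k <- function(run, delta_threshold = 0.1, consensus_floor = 0.9) {
  stopifnot(inherits(run, "consensus_run"))
  ks <- as.integer(names(run$k))
  min_cc <- vapply(run$k, function(e) {
    if (anyNA(e$cluster_consensus)) NA_real_ else min(e$cluster_consensus)
  }, numeric(1))
  report <- data.frame(
    k = ks,
    area = vapply(run$k, function(e) e$area, numeric(1)),
    delta_area = vapply(run$k, function(e) e$delta_area, numeric(1)),
    min_cluster_consensus = min_cc,
    mean_cluster_consensus = vapply(run$k, function(e) {
      mean(e$cluster_consensus, na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL
  )
  report$qualifies <- report$delta_area > delta_threshold &
    !is.na(report$min_cluster_consensus) &
    report$min_cluster_consensus >= consensus_floor
  if (any(report$qualifies)) {
    k_star <- max(report$k[report$qualifies])
    low <- FALSE
  } else {
    k_star <- report$k[which.max(report$mean_cluster_consensus)]
    low <- TRUE
  }
  list(k_star = as.integer(k_star), low_confidence = low, report = report)
}

#' Name two consensus clusters M1/M2 by their response score
#'
#' The cluster with the higher mean response score is named M2 (the
#' stronger-response subtype), the other M1. Equal means are broken by size
#' (the larger cluster becomes M1) with a warning.
#'
#' @param assignments two-cluster integer assignments per sample.
#' @param score per-sample numeric response score, same order.
#' @return character vector of "M1"/"M2" per sample.
#' @export
label_subtypes <- function(assignments, score) {
  if (length(assignments) != length(score)) {
    stop("assignments and score lengths differ")
  }
  cl <- sort(unique(assignments))
  if (length(cl) != 2) stop("unsupported: subtype labelling requires k = 2")
  m <- vapply(cl, function(c) mean(score[assignments == c]), numeric(1))
  if (m[1] == m[2]) {
    warning("equal mean scores; tie broken by cluster size (larger = M1)")
    sizes <- vapply(cl, function(c) sum(assignments == c), numeric(1))
    m1 <- cl[which.max(sizes)]
  } else {
    m1 <- cl[which.min(m)]
  }
  ifelse(assignments == m1, "M1", "M2")
}
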