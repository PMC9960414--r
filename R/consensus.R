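# Resampled consensus clustering of genes, with CDF/delta-area diagnostics.
# For each repetition a fraction p_item of genes (and p_feature of samples)
# is subsampled without replacement, clustered hierarchically (Ward.D2 on
# Euclidean distance) and cut at each k; the consensus matrix entry for two
# genes is the fraction of co-sampled repetitions in which they landed in
# the same cluster. Final per-k labels come from hierarchical clustering of
# 1 - M as a distance. Implemented from scratch on top of stats::hclust.

#' Consensus clustering configuration
#'
#' Defaults follow the published run: 100 repetitions, pItem = 0.8,
#' pFeature = 1, Euclidean distance with Ward.D2 linkage in the inner loop,
#' k scanned over 2..5 with k = 4 used by the main pipeline.
#'
#' @param k_values integer vector of cluster numbers (all >= 2).
#' @param reps number of subsampling repetitions (>= 1).
#' @param p_item fraction of items (genes) subsampled per rep, in (0, 1].
#' @param p_feature fraction of features (samples) subsampled per rep.
#' @param linkage_final linkage used on `1 - M` for the final labels:
#'   `"average"` (default) or `"ward"`.
#' @param seed integer seed; per-rep seeds are derived from it by a
#'   counter, so results do not depend on rep order.
#' @return validated list of class `consensus_config`.
#' @export
consensus_config <- function(k_values = 2:5, reps = 100, p_item = 0.8,
                             p_feature = 1, linkage_final = c("average", "ward"),
                             seed = 1L) {
  linkage_final <- match.arg(linkage_final)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 2L)) stop("every k must be >= 2")
  if (reps < 1L) stop("reps must be >= 1")
  if (p_item <= 0 || p_item > 1 || p_feature <= 0 || p_feature > 1)
    stop("p_item and p_feature must lie in (0, 1]")
  structure(list(k_values = k_values, reps = as.integer(reps),
                 p_item = p_item, p_feature = p_feature,
                 distance = "euclidean", linkage_inner = "ward",
                 linkage_final = linkage_final, seed = as.integer(seed)),
            class = "consensus_config")
}

#' Resampled consensus clustering of genes
#'
#' @param expr_centered an `ExpressionMatrix` (typically `centered`); items
#'   are genes (rows), features are samples (columns). Needs at least
#'   `max(k_values) + 1` genes.
#' @param config a [consensus_config()].
#' @return object of class `ConsensusResult`: list with `k_values`,
#'   `per_k` (per k: `consensus_matrix`, `labels` named integer vector,
#'   `pair_sample_counts`), `diagnostics` (data.frame k/auc/delta_area)
#'   and `config`.
#' @export
consensus_cluster <- function(expr_centered, config = consensus_config()) {
  stopifnot(inherits(expr_centered, "ExpressionMatrix"),
            inherits(config, "consensus_config"))
  x <- expr_centered$values
  n <- nrow(x); m <- ncol(x)
  ks <- config$k_values
  if (n < max(ks) + 1L)
    stop("need at least max(k)+1 = ", max(ks) + 1L, " genes, got ", n)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L)))
    stop("degenerate input: all gene rows identical (",
         paste(rownames(x), collapse = ", "), ")")

  n_item <- ceiling(config$p_item * n)
  n_feat <- ceiling(config$p_feature * m)
  cosample <- matrix(0L, n, n)
  cocluster <- lapply(ks, function(k) matrix(0L, n, n))
  names(cocluster) <- as.character(ks)

  for (r in seq_len(config$reps)) {
    set.seed(derive_seed(config$seed, paste0("rep", r)))
    items <- sort(sample.int(n, n_item))
    feats <- sort(sample.int(m, n_feat))
    sub <- x[items, feats, drop = FALSE]
    hc <- stats::hclust(stats::dist(sub, method = "euclidean"),
                        method = "ward.D2")
    cosample[items, items] <- cosample[items, items] + 1L
    for (k in ks) {
      ct <- stats::cutree(hc, k = k)
      same <- outer(ct, ct, "==")
      ck <- as.character(k)
      cocluster[[ck]][items, items] <-
        cocluster[[ck]][items, items] + (same * 1L)
    }
  }

  never <- cosample == 0 & upper.tri(cosample)
  if (any(never))
    warning(sum(never), " gene pair(s) never co-sampled; consensus set to 0")

  per_k <- lapply(ks, function(k) {
    M <- cocluster[[as.character(k)]] / pmax(cosample, 1L)
    M[cosample == 0] <- 0
    diag(M) <- 1
    dimnames(M) <- list(rownames(x), rownames(x))
    hc_final <- stats::hclust(
      stats::as.dist(1 - M),
      method = if (config$linkage_final == "ward") "ward.D2" else "average")
    labels <- stats::cutree(hc_final, k = k)
    names(labels) <- rownames(x)
    cs <- cosample
    dimnames(cs) <- dimnames(M)
    list(k = k, consensus_matrix = M, labels = labels,
         pair_sample_counts = cs)
  })
  names(per_k) <- as.character(ks)

  res <- structure(list(k_values = ks, per_k = per_k, config = config),
                   class = "ConsensusResult")
  res$diagnostics <- cdf_delta_area(res)
  res
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult over k =", paste(x$k_values, collapse = ", "), "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' CDF area and delta-area diagnostics
#'
#' For each k, the empirical CDF of the upper-triangle consensus values is
#' integrated exactly over \[0, 1\] (step-function integral, equal to
#' `1 - mean(values)`); `delta_area(k)` is the relative change
#' `(auc_k - auc_{k-1}) / auc_{k-1}`, and for the smallest k it is defined
#' as `auc_k` itself. A clean two-point consensus distribution (all values
#' 0 or 1) gives `auc` equal to the fraction of zero pairs.
#'
#' @param result a `ConsensusResult`.
#' @return data.frame with columns `k`, `auc`, `delta_area`.
#' @export
cdf_delta_area <- function(result) {
  stopifnot(inherits(result, "ConsensusResult"))
  aucs <- vapply(result$per_k, function(pk) {
    v <- pk$consensus_matrix[upper.tri(pk$consensus_matrix)]
    .ecdf_area(v)
  }, numeric(1))
  ks <- result$k_values
  delta <- c(aucs[1], diff(aucs) / aucs[-length(aucs)])
  data.frame(k = ks, auc = unname(aucs), delta_area = unname(delta))
}

# exact integral over [0,1] of the ECDF of values in [0,1]:
# sum over jump points x_i of (x_{i+1} - x_i) * F(x_i), grid closed at 0, 1
.ecdf_area <- function(v) {
  stopifnot(all(v >= 0 & v <= 1))
  xs <- sort(unique(c(0, v, 1)))
  F <- vapply(xs, function(q) mean(v <= q), numeric(1))
  sum(diff(xs) * F[-length(xs)])
}
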