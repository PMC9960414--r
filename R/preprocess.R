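# Normalization and filtering ahead of clustering: TPM + log10 transform,
# tumor-purity filter (strict < threshold removal), fold-change gene
# selection, and gene-wise location/scale so the quadrant thresholds at 0
# are cohort-relative.

#' Log-transform expression to log10(TPM + 1)
#'
#' Raw counts are first rescaled per sample to sum to 1e6 (input assumed
#' pre-length-normalized; no gene-length model); TPM input is transformed
#' directly. The map `v -> log10(v + 1)` is monotone and zero-preserving.
#'
#' @param expr an `ExpressionMatrix` with `scale_tag` `"counts"` or
#'   `"tpm"`.
#' @return an `ExpressionMatrix` with `scale_tag = "log_tpm"`.
#' @export
tpm_log_transform <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!expr$scale_tag %in% c("counts", "tpm"))
    stop("tpm_log_transform expects counts or tpm input, got '",
         expr$scale_tag, "'")
  v <- expr$values
  if (any(v < 0, na.rm = TRUE)) stop("negative expression values")
  if (any(!is.finite(v))) stop("non-finite expression values")
  if (expr$scale_tag == "counts") {
    cs <- colSums(v)
    if (any(cs == 0)) stop("sample with zero total counts")
    v <- sweep(v, 2, cs, "/") * 1e6
  }
  expression_matrix(log10(v + 1), "log_tpm")
}

#' Remove samples with low tumor purity
#'
#' Samples with purity strictly below `purity_min` are removed; samples
#' with missing purity are retained and counted in the report (only
#' known-low-purity samples are filtered).
#'
#' @param expr an `ExpressionMatrix`; every sample must have a clinical row.
#' @param clinical a `ClinicalTable` with a `purity` column (may be absent,
#'   in which case all samples count as missing-purity).
#' @param purity_min removal threshold in \[0,1\] (default 0.30).
#' @return list with `expression`, `clinical` (filtered, original order)
#'   and `report` (`n_removed`, `n_missing`, `removed_ids`).
#' @export
filter_low_purity <- function(expr, clinical, purity_min = 0.30) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (purity_min < 0 || purity_min > 1) stop("purity_min must be in [0,1]")
  ids <- sample_ids(expr)
  miss_clin <- setdiff(ids, clinical$sample_id)
  if (length(miss_clin))
    stop("samples without clinical rows: ", paste(miss_clin, collapse = ", "))
  purity <- if ("purity" %in% colnames(clinical))
    clinical$purity[match(ids, clinical$sample_id)] else rep(NA_real_, length(ids))
  drop <- !is.na(purity) & purity < purity_min
  keep_ids <- ids[!drop]
  if (!length(keep_ids)) warning("all samples removed by purity filter")
  out_expr <- if (length(keep_ids)) em_subset(expr, samples = keep_ids)
              else expression_matrix(expr$values[, 0, drop = FALSE], expr$scale_tag)
  out_clin <- clinical[clinical$sample_id %in% keep_ids, , drop = FALSE]
  rownames(out_clin) <- NULL
  list(expression = out_expr,
       clinical = out_clin,
       report = list(n_removed = sum(drop),
                     n_missing = sum(is.na(purity)),
                     removed_ids = ids[drop]))
}

#' Select differentially expressed genes by log2 fold change
#'
#' Group means are computed on the stored log10 scale and converted to
#' log2 units; genes with `|mean(A) - mean(B)| >= de_log2fc_min` (inclusive
#' at the threshold) are returned.
#'
#' @param expr_log an `ExpressionMatrix` on a log scale (`log_tpm` or
#'   `centered`).
#' @param group_a,group_b disjoint non-empty sample id vectors.
#' @param de_log2fc_min inclusive log2 fold-change threshold (default 1).
#' @return character vector of selected gene ids (matrix order).
#' @export
select_de_genes <- function(expr_log, group_a, group_b, de_log2fc_min = 1) {
  stopifnot(inherits(expr_log, "ExpressionMatrix"))
  if (!expr_log$scale_tag %in% c("log_tpm", "centered"))
    stop("select_de_genes expects a log-scale matrix")
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("sample groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  a <- em_subset(expr_log, samples = group_a)$values
  b <- em_subset(expr_log, samples = group_b)$values
  lfc <- (rowMeans(a) - rowMeans(b)) / log10(2)  # log10 -> log2 units
  gene_ids(expr_log)[abs(lfc) >= de_log2fc_min - 1e-9]
}

#' Gene-wise centering and scaling
#'
#' Centers each gene at its median (default) or mean and optionally scales
#' to unit SD or unit MAD. Constant rows become all zeros with a warning
#' (scale left at 1). This is the "gene-wise location scaling" used as
#' per-cohort batch correction, and it is what makes the quadrant rule's
#' thresholds at 0 meaningful.
#'
#' @param expr_log an `ExpressionMatrix` on a log scale, >= 2 samples.
#' @param centering `"median"` (default) or `"mean"`.
#' @param scaling `"sd"` (default), `"mad"`, or `"none"`.
#' @return an `ExpressionMatrix` with `scale_tag = "centered"`.
#' @export
center_scale_genes <- function(expr_log,
                               centering = c("median", "mean"),
                               scaling = c("sd", "mad", "none")) {
  stopifnot(inherits(expr_log, "ExpressionMatrix"))
  centering <- match.arg(centering)
  scaling <- match.arg(scaling)
  v <- expr_log$values
  if (ncol(v) < 2L) stop("center_scale_genes needs >= 2 samples")
  ctr <- if (centering == "median") apply(v, 1, stats::median) else rowMeans(v)
  v <- v - ctr
  if (scaling != "none") {
    sc <- switch(scaling,
                 sd = apply(v, 1, stats::sd),
                 mad = apply(v, 1, stats::mad))
    flat <- sc == 0 | !is.finite(sc)
    if (any(flat)) {
      warning("constant gene row(s) left at 0: ",
              paste(rownames(v)[flat], collapse = ", "))
      sc[flat] <- 1
    }
    v <- v / sc
  }
  expression_matrix(v, "centered")
}
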