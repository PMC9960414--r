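#' ExpressionMatrix container
#'
#' A genes x samples numeric matrix plus a declared expression scale.
#' All pipeline stages consume and return this type so that the scale a
#' value lives on (raw counts, TPM, log10(TPM+1), or gene-centered) is
#' always explicit and checkable.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param scale_tag one of `"counts"`, `"tpm"`, `"log_tpm"`, `"centered"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `scale_tag`.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("S1", "S2")))
#' expression_matrix(m, "tpm")
#' @export
expression_matrix <- function(values,
                              scale_tag = c("counts", "tpm", "log_tpm", "centered")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (scale_tag != "counts" && any(!is.finite(values)))
    stop("non-finite values not allowed on scale '", scale_tag, "'")
  structure(list(values = values, scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of ids, in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by gene and/or sample ids
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#'   Missing ids are an error; order of the result follows the request.
#' @return an `ExpressionMatrix` with the same `scale_tag`.
#' @export
em_subset <- function(x, genes = gene_ids(x), samples = sample_ids(x)) {
  bad_g <- setdiff(genes, gene_ids(x))
  if (length(bad_g)) stop("genes not in matrix: ", paste(bad_g, collapse = ", "))
  bad_s <- setdiff(samples, sample_ids(x))
  if (length(bad_s)) stop("samples not in matrix: ", paste(bad_s, collapse = ", "))
  expression_matrix(x$values[genes, samples, drop = FALSE], x$scale_tag)
}
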