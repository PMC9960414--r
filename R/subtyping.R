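# Core co-expressed cluster selection and the quadrant subtype rule.
# A cluster is a candidate "core" for a pathway set when at least half of
# its members come from that set; among candidates the most homogeneous
# cluster wins (ties: larger cluster, then lowest cluster id). Samples are
# then scored by the median centered expression over each core and
# classified by quadrant: boundary 0 belongs to the "<= 0" side.

#' Select core co-expressed gene clusters
#'
#' @param labels named integer vector, gene -> cluster id (e.g. from
#'   [consensus_cluster()] at k = 4). Every gene must belong to exactly one
#'   of the two sets.
#' @param gene_sets list of exactly two [gene_set()] objects: the
#'   glycolysis set first, the cholesterol-biosynthesis set second.
#' @param min_composition minimum fraction of a cluster's members that
#'   must come from a set for the cluster to be a candidate core
#'   (default 0.5, inclusive).
#' @param composition_of by default (`"cluster"`) composition is the
#'   fraction of the cluster's members belonging to the set; the
#'   alternative reading (`"set"`: fraction of the set captured by the
#'   cluster) is available behind this flag.
#' @return object of class `CoreClusters`: list with `gly_core`,
#'   `chol_core` (gene vectors), `homogeneity` (named winning
#'   compositions), `composition` (per-cluster data.frame) and the winning
#'   cluster ids.
#' @export
select_core_clusters <- function(labels, gene_sets, min_composition = 0.5,
                                 composition_of = c("cluster", "set")) {
  composition_of <- match.arg(composition_of)
  if (length(gene_sets) != 2L)
    stop("gene_sets must hold exactly two sets (glycolysis, cholesterol)")
  gly <- gene_sets[[1]]$genes; chol <- gene_sets[[2]]$genes
  genes <- names(labels)
  if (is.null(genes)) stop("labels must be a named vector (gene -> cluster)")
  in_gly <- genes %in% gly; in_chol <- genes %in% chol
  bad <- genes[in_gly == in_chol]  # in both or in neither
  if (length(bad))
    stop("genes not in exactly one set: ", paste(bad, collapse = ", "))

  cl_ids <- sort(unique(labels))
  comp <- do.call(rbind, lapply(cl_ids, function(cl) {
    members <- labels == cl
    n_gly <- sum(members & in_gly); n_chol <- sum(members & in_chol)
    size <- sum(members)
    data.frame(cluster = cl, size = size, n_gly = n_gly, n_chol = n_chol,
               comp_gly = if (composition_of == "cluster") n_gly / size
                          else n_gly / length(gly),
               comp_chol = if (composition_of == "cluster") n_chol / size
                           else n_chol / length(chol))
  }))

  candidates <- function(col) {
    cand <- comp[comp[[col]] >= min_composition - 1e-12, , drop = FALSE]
    cand[order(-cand[[col]], -cand$size, cand$cluster), , drop = FALSE]
  }
  cand_gly <- candidates("comp_gly")
  cand_chol <- candidates("comp_chol")
  if (!nrow(cand_gly))
    stop("core selection failed: no candidate cluster for set '",
         gene_sets[[1]]$name, "'")
  if (!nrow(cand_chol))
    stop("core selection failed: no candidate cluster for set '",
         gene_sets[[2]]$name, "'")

  win_gly <- cand_gly$cluster[1]
  win_chol <- cand_chol$cluster[1]
  if (win_gly == win_chol) {
    # one cluster cannot serve both sets; give it to the set without an
    # alternative candidate
    alt_gly <- cand_gly$cluster[cand_gly$cluster != win_gly]
    alt_chol <- cand_chol$cluster[cand_chol$cluster != win_chol]
    if (length(alt_gly) && !length(alt_chol)) win_gly <- alt_gly[1]
    else if (length(alt_chol) && !length(alt_gly)) win_chol <- alt_chol[1]
    else if (length(alt_gly) && length(alt_chol)) {
      # both have alternatives: keep the shared cluster for the set it
      # represents better, fall back for the other
      if (comp$comp_gly[comp$cluster == win_gly] >=
          comp$comp_chol[comp$cluster == win_chol]) win_chol <- alt_chol[1]
      else win_gly <- alt_gly[1]
    } else
      stop("core selection failed: a single cluster is the only candidate ",
           "for both sets")
  }

  gly_core <- genes[labels == win_gly & in_gly]
  chol_core <- genes[labels == win_chol & in_chol]
  structure(list(
    gly_core = gly_core, chol_core = chol_core,
    cluster_gly = win_gly, cluster_chol = win_chol,
    homogeneity = c(gly = comp$comp_gly[comp$cluster == win_gly],
                    chol = comp$comp_chol[comp$cluster == win_chol]),
    composition = comp), class = "CoreClusters")
}

#' @export
print.CoreClusters <- function(x, ...) {
  cat(sprintf("CoreClusters: %d glycolytic (homogeneity %.2f), %d cholesterogenic (homogeneity %.2f)\n",
              length(x$gly_core), x$homogeneity["gly"],
              length(x$chol_core), x$homogeneity["chol"]))
  invisible(x)
}

#' Per-sample pathway scores
#'
#' The glycolytic (cholesterogenic) score of a sample is the median of its
#' centered expression over the core glycolytic (cholesterogenic) genes.
#'
#' @param expr_centered an `ExpressionMatrix` (scale `centered`).
#' @param core a `CoreClusters` object; all core genes must be present.
#' @return data.frame with columns `sample_id`, `gly_score`, `chol_score`.
#' @export
compute_pathway_scores <- function(expr_centered, core) {
  stopifnot(inherits(expr_centered, "ExpressionMatrix"),
            inherits(core, "CoreClusters"))
  missing <- setdiff(c(core$gly_core, core$chol_core), gene_ids(expr_centered))
  if (length(missing))
    stop("core genes absent from matrix: ", paste(missing, collapse = ", "))
  v <- expr_centered$values
  g <- apply(v[core$gly_core, , drop = FALSE], 2, stats::median)
  c_ <- apply(v[core$chol_core, , drop = FALSE], 2, stats::median)
  data.frame(sample_id = sample_ids(expr_centered),
             gly_score = unname(g), chol_score = unname(c_),
             stringsAsFactors = FALSE)
}

#' Assign metabolic subtypes by the quadrant rule
#'
#' quiescent: gly <= 0 and chol <= 0; glycolytic: gly > 0 and chol <= 0;
#' cholesterogenic: gly <= 0 and chol > 0; mixed: gly > 0 and chol > 0.
#' Boundary 0 belongs to the "<= 0" side.
#'
#' @param scores data.frame from [compute_pathway_scores()].
#' @return the input data.frame with a `subtype` factor column added
#'   (levels in [metabolic_subtypes()] order).
#' @export
assign_subtype <- function(scores) {
  req <- c("sample_id", "gly_score", "chol_score")
  if (!all(req %in% colnames(scores)))
    stop("scores must have columns ", paste(req, collapse = ", "))
  g <- scores$gly_score; c_ <- scores$chol_score
  if (any(is.na(g) | is.na(c_) | !is.finite(g) | !is.finite(c_)))
    stop("non-finite pathway score")
  sub <- ifelse(g > 0,
                ifelse(c_ > 0, "mixed", "glycolytic"),
                ifelse(c_ > 0, "cholesterogenic", "quiescent"))
  out <- scores
  out$subtype <- factor(sub, levels = metabolic_subtypes())
  out
}

#' Cross-tabulate subtype calls against an external labeling
#'
#' @param calls data.frame from [assign_subtype()].
#' @param external_labels named vector, sample id -> external label.
#' @return list with `table` (subtype x external counts over the
#'   overlapping samples), `proportions` (row proportions) and `test`
#'   (a [contingency_test()] result, or NULL with a warning when either
#'   margin is degenerate).
#' @export
cross_tabulate <- function(calls, external_labels) {
  common <- intersect(calls$sample_id, names(external_labels))
  if (!length(common)) stop("no overlapping samples")
  sub <- calls$subtype[match(common, calls$sample_id)]
  ext <- external_labels[common]
  tab <- table(subtype = factor(sub, levels = metabolic_subtypes()),
               external = ext)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  test <- NULL
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    warning("degenerate contingency table; test skipped")
  else
    test <- contingency_test(unclass(tab))
  list(table = tab,
       proportions = prop.table(tab, margin = 1),
       test = test)
}
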