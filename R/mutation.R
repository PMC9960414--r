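# CNV event calling (from integer copy status and from SEG segments),
# gene-level alteration matrices, and cross-subtype contingency testing.
# Thresholds: copy status >= 3 amplified / <= 1 deleted (inclusive);
# segment events need >= 10 supporting probes (inclusive) AND
# seg.mean strictly > 0.2 (amplified) or strictly < -0.2 (deleted).

#' Default gene panel for mutation analysis
#'
#' The five most frequently mutated genes examined across the metabolic
#' subtypes.
#' @return character vector.
#' @export
default_gene_panel <- function() c("TP53", "CDKN2A", "PIK3CA", "LRP1B", "FLG")

#' Call CNV events from integer copy status
#'
#' @param copy_status samples x genes integer matrix of absolute copy
#'   numbers (rownames = sample ids, colnames = genes).
#' @return data.frame of `CnvCall`s: `sample_id`, `gene`, `direction`
#'   (`amplified`/`deleted`), `source = "ploidy"`. Status 2 yields no call.
#' @export
call_cnv_from_ploidy <- function(copy_status) {
  if (!is.matrix(copy_status)) stop("copy_status must be a matrix")
  if (any(copy_status < 0)) stop("negative copy status")
  if (is.null(rownames(copy_status)) || is.null(colnames(copy_status)))
    stop("copy_status needs sample rownames and gene colnames")
  amp <- which(copy_status >= 3, arr.ind = TRUE)
  del <- which(copy_status <= 1, arr.ind = TRUE)
  build <- function(idx, dir) {
    if (!nrow(idx)) return(NULL)
    data.frame(sample_id = rownames(copy_status)[idx[, 1]],
               gene = colnames(copy_status)[idx[, 2]],
               direction = dir, source = "ploidy",
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(amp, "amplified"), build(del, "deleted"))
  if (is.null(out))
    out <- data.frame(sample_id = character(), gene = character(),
                      direction = character(), source = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call CNV events from copy-number segments
#'
#' A segment is an event when it has `min_probes` or more supporting
#' probes (inclusive) and |seg.mean| strictly above `mean_thresh`. Event
#' coordinates are mapped to genes by any overlap (>= 1 bp, 1-based
#' inclusive). A gene/sample pair hit by both an amplification and a
#' deletion keeps both calls, with a message.
#'
#' @param segments a `SegmentTable`.
#' @param coords a `GeneCoordinates` table (1-based inclusive).
#' @param min_probes inclusive probe-count threshold (default 10).
#' @param mean_thresh strict |seg.mean| threshold (default 0.2).
#' @return data.frame of `CnvCall`s with `source = "segment"`.
#' @export
call_cnv_from_segments <- function(segments, coords,
                                   min_probes = 10, mean_thresh = 0.2) {
  stopifnot(inherits(segments, "SegmentTable") || is.data.frame(segments),
            inherits(coords, "GeneCoordinates") || is.data.frame(coords))
  if (nrow(segments) && nrow(coords) &&
      !length(intersect(unique(segments$chrom), unique(coords$chrom))))
    stop("chromosome naming mismatch between segments and gene coordinates: ",
         "segments use {", paste(utils::head(unique(segments$chrom), 5),
                                 collapse = ", "),
         "}, coordinates use {", paste(utils::head(unique(coords$chrom), 5),
                                       collapse = ", "), "}")
  ev <- segments[segments$num_probes >= min_probes &
                   abs(segments$seg_mean) > mean_thresh, , drop = FALSE]
  out <- list()
  for (ch in unique(ev$chrom)) {
    e <- ev[ev$chrom == ch, , drop = FALSE]
    g <- coords[coords$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    for (i in seq_len(nrow(e))) {
      hit <- g$start <= e$end[i] & g$end >= e$start[i]
      if (!any(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = e$sample_id[i], gene = g$gene[hit],
        direction = if (e$seg_mean[i] > 0) "amplified" else "deleted",
        source = "segment", stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) unique(do.call(rbind, out))
           else data.frame(sample_id = character(), gene = character(),
                           direction = character(), source = character(),
                           stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  key <- paste(calls$sample_id, calls$gene)
  dup_dir <- tapply(calls$direction, key, function(d) length(unique(d)) > 1)
  if (any(dup_dir, na.rm = TRUE))
    message("call_cnv_from_segments: ", sum(dup_dir, na.rm = TRUE),
            " gene/sample pair(s) carry both amplification and deletion")
  calls
}

#' Build a binary gene alteration matrix
#'
#' @param mutations a `MutationTable` (SNV/INDEL records).
#' @param cnv data.frame of CNV calls (possibly from both sources; when
#'   both are supplied, pass their row-bound union).
#' @param samples sample id universe (rows of the result). Samples absent
#'   from the mutation data are assumed wild-type.
#' @param genes gene panel (default [default_gene_panel()]).
#' @return object of class `GeneMutationMatrix`: list of samples x genes
#'   binary matrices `snv_indel`, `amplified`, `deleted`, and `altered`
#'   (their elementwise OR).
#' @export
build_mutation_matrix <- function(mutations, cnv, samples,
                                  genes = default_gene_panel()) {
  if (!length(genes)) stop("gene panel must be non-empty")
  mk <- function() matrix(0L, length(samples), length(genes),
                          dimnames = list(samples, genes))
  snv <- mk(); amp <- mk(); del <- mk()
  fill <- function(M, sid, gid) {
    keep <- sid %in% samples & gid %in% genes
    if (any(keep)) M[cbind(sid[keep], gid[keep])] <- 1L
    M
  }
  if (nrow(mutations))
    snv <- fill(snv, mutations$sample_id, mutations$gene)
  if (nrow(cnv)) {
    a <- cnv[cnv$direction == "amplified", ]
    d <- cnv[cnv$direction == "deleted", ]
    amp <- fill(amp, a$sample_id, a$gene)
    del <- fill(del, d$sample_id, d$gene)
  }
  altered <- pmin(snv + amp + del, 1L)
  structure(list(snv_indel = snv, amplified = amp, deleted = del,
                 altered = altered), class = "GeneMutationMatrix")
}

#' Chi-square / Monte-Carlo contingency test
#'
#' Pearson chi-square without continuity correction. With
#' `method = "auto"` (default) the p-value falls back to a seeded
#' Monte-Carlo conditional test (random tables with fixed margins via
#' `r2dtable`) when any expected count is below 5 — the exact-test
#' fallback for sparse tables, labelled `"fisher"` in the result.
#'
#' @param tab integer matrix (r x c contingency table).
#' @param method `"auto"`, `"chi2"`, or `"fisher"` (force Monte-Carlo).
#' @param mc_reps Monte-Carlo table count (default 10000).
#' @param seed integer seed for the Monte-Carlo draw (default 1).
#' @return list with `statistic`, `df`, `p_value`, `test_used`,
#'   `expected`.
#' @export
contingency_test <- function(tab, method = c("auto", "chi2", "fisher"),
                             mc_reps = 10000, seed = 1L) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("table has an empty margin")
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  use_mc <- method == "fisher" ||
    (method == "auto" && any(expected < 5))
  if (use_mc) {
    set.seed(seed)
    sims <- stats::r2dtable(mc_reps, rs, cs)
    sim_stat <- vapply(sims, function(s) sum((s - expected)^2 / expected),
                       numeric(1))
    p <- (1 + sum(sim_stat >= stat - 1e-9)) / (mc_reps + 1)
    used <- "fisher"
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    used <- "chi2"
  }
  list(statistic = stat, df = df, p_value = p, test_used = used,
       expected = expected)
}

#' Test gene alteration frequencies across subtypes
#'
#' For each panel gene, builds the 2 x k (altered/wild x subtype) table
#' and applies [contingency_test()]; q-values are Benjamini-Hochberg
#' across the panel.
#'
#' @param matrix_ a `GeneMutationMatrix`.
#' @param calls data.frame from [assign_subtype()] (needs `sample_id`,
#'   `subtype`); only samples present in both are tested.
#' @param mc_seed seed forwarded to the Monte-Carlo fallback.
#' @return data.frame with `gene`, `statistic`, `df`, `p_value`,
#'   `test_used`, `q_value`, plus per-subtype altered frequencies; the
#'   2 x k tables are attached as attribute `"tables"`.
#' @export
test_gene_by_subtype <- function(matrix_, calls, mc_seed = 1L) {
  stopifnot(inherits(matrix_, "GeneMutationMatrix"))
  samples <- intersect(rownames(matrix_$altered), calls$sample_id)
  if (!length(samples)) stop("no overlapping samples")
  sub <- as.character(calls$subtype[match(samples, calls$sample_id)])
  present <- intersect(metabolic_subtypes(), unique(sub))
  if (length(present) < 2L) stop("all samples belong to one subtype")
  alt <- matrix_$altered[samples, , drop = FALSE]
  tabs <- list()
  rows <- lapply(colnames(alt), function(g) {
    tab <- vapply(present, function(s) {
      a <- sum(alt[sub == s, g]); c(altered = a, wild = sum(sub == s) - a)
    }, numeric(2))
    tabs[[g]] <<- tab
    ct <- contingency_test(tab, seed = derive_seed(mc_seed, g))
    freqs <- tab["altered", ] / colSums(tab)
    names(freqs) <- paste0("freq_", present)
    data.frame(gene = g, statistic = ct$statistic, df = ct$df,
               p_value = ct$p_value, test_used = ct$test_used,
               t(freqs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "tables") <- tabs
  out
}
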