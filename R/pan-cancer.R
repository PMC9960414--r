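# Pan-cancer screening loop: for every cohort, re-run the per-cohort
# pipeline (gene-wise location scaling, consensus clustering at k = 4,
# core-cluster selection) and apply the stated gates — at least 100
# samples (inclusive) and >= 75% homogeneity in BOTH core clusters —
# then assign subtypes and test survival separation.

#' Screen cohorts for coherent metabolic gene clusters
#'
#' Per cohort: drop if `n < min_samples` (a cohort with exactly
#' `min_samples` samples is kept); log-transform if needed and
#' center/scale genes within the cohort; run consensus clustering at
#' k = 4; select core clusters; drop if either core's homogeneity is
#' below `homogeneity_min`; assign quadrant subtypes; run the 4-group
#' log-rank test on samples surviving the OS >= 1 month filter. All
#' failures become report rows, never errors. Deterministic under
#' `seed` (each cohort's clustering seed is derived from the master seed
#' and the cancer code, so cohort order is irrelevant).
#'
#' @param cohorts named list: cancer code -> list with `expression`
#'   (`ExpressionMatrix`, counts/tpm/log_tpm) and `clinical`
#'   (`ClinicalTable`).
#' @param gene_sets two [gene_set()]s (glycolysis, cholesterol); default
#'   [default_gene_sets()].
#' @param min_samples inclusive minimum cohort size (default 100).
#' @param homogeneity_min minimum winning composition for both cores
#'   (default 0.75).
#' @param consensus_cfg base [consensus_config()]; its seed is re-derived
#'   per cohort from `seed`.
#' @param seed master seed.
#' @return object of class `CohortScreen`: list with `report` (one row
#'   per cohort: gates, homogeneities, subtype counts, log-rank result)
#'   and `details` (per passing cohort: core clusters and subtype calls).
#' @export
screen_cohorts <- function(cohorts, gene_sets = default_gene_sets(),
                           min_samples = 100, homogeneity_min = 0.75,
                           consensus_cfg = consensus_config(k_values = 4),
                           seed = 1L) {
  if (!length(cohorts)) stop("need at least one cohort")
  codes <- names(cohorts)
  if (is.null(codes)) stop("cohorts must be a named list")
  subtype_cols <- paste0("n_", metabolic_subtypes())
  details <- list()
  rows <- lapply(codes, function(code) {
    co <- cohorts[[code]]
    expr <- co$expression
    n <- length(sample_ids(expr))
    row <- data.frame(cancer_code = code, n_samples = n,
                      passed_min_samples = n >= min_samples,
                      core_gly_found = NA, core_chol_found = NA,
                      homogeneity_gly = NA_real_, homogeneity_chol = NA_real_,
                      passed_homogeneity = NA,
                      stringsAsFactors = FALSE)
    row[subtype_cols] <- NA_integer_
    row$logrank_statistic <- NA_real_
    row$logrank_p <- NA_real_
    if (!row$passed_min_samples) return(row)

    if (expr$scale_tag %in% c("counts", "tpm")) expr <- tpm_log_transform(expr)
    centered <- center_scale_genes(expr)
    keep <- intersect(gene_ids(centered),
                      c(gene_sets[[1]]$genes, gene_sets[[2]]$genes))
    centered <- em_subset(centered, genes = keep)
    cfg <- consensus_cfg
    cfg$seed <- derive_seed(seed, code)
    cons <- consensus_cluster(centered, cfg)
    labels <- cons$per_k[[as.character(max(cfg$k_values))]]$labels

    core <- tryCatch(select_core_clusters(labels, gene_sets),
                     error = function(e) e)
    if (inherits(core, "error")) {
      failed_set <- if (grepl(gene_sets[[1]]$name, conditionMessage(core),
                              fixed = TRUE)) "gly" else "chol"
      row$core_gly_found <- failed_set != "gly"
      row$core_chol_found <- failed_set != "chol"
      row$passed_homogeneity <- FALSE
      return(row)
    }
    row$core_gly_found <- TRUE
    row$core_chol_found <- TRUE
    row$homogeneity_gly <- unname(core$homogeneity["gly"])
    row$homogeneity_chol <- unname(core$homogeneity["chol"])
    row$passed_homogeneity <- all(core$homogeneity >= homogeneity_min)
    if (!row$passed_homogeneity) return(row)

    calls <- assign_subtype(compute_pathway_scores(centered, core))
    counts <- table(calls$subtype)
    row[subtype_cols] <- as.integer(counts[metabolic_subtypes()])
    details[[code]] <<- list(core = core, calls = calls)

    clin <- filter_min_followup(co$clinical)
    clin <- clin[clin$sample_id %in% calls$sample_id, , drop = FALSE]
    sub <- calls$subtype[match(clin$sample_id, calls$sample_id)]
    if (length(unique(sub)) >= 2L && sum(clin$os_event) >= 1) {
      lr <- logrank_test_by(clin$os_months, clin$os_event, sub)
      row$logrank_statistic <- lr$statistic
      row$logrank_p <- lr$p_value
    }
    row
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, details = details),
            class = "CohortScreen")
}

#' @export
print.CohortScreen <- function(x, ...) {
  print(x$report[, c("cancer_code", "n_samples", "passed_min_samples",
                     "passed_homogeneity", "logrank_statistic",
                     "logrank_p")], row.names = FALSE)
  invisible(x)
}

#' Rank screened cohorts by survival separation
#'
#' @param screen a `CohortScreen` (or its `report` data.frame).
#' @return data.frame (`cancer_code`, `logrank_statistic`, `logrank_p`)
#'   restricted to cohorts with a survival test, sorted by statistic
#'   descending. Empty with a warning when no cohort passed.
#' @export
rank_survival_separation <- function(screen) {
  report <- if (inherits(screen, "CohortScreen")) screen$report else screen
  ok <- !is.na(report$logrank_statistic)
  if (!any(ok)) {
    warning("no passing cohorts with a survival test")
    return(data.frame(cancer_code = character(),
                      logrank_statistic = numeric(),
                      logrank_p = numeric()))
  }
  out <- report[ok, c("cancer_code", "logrank_statistic", "logrank_p")]
  out <- out[order(-out$logrank_statistic), ]
  rownames(out) <- NULL
  out
}
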