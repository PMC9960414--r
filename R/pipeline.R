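# End-to-end single-cohort pipeline and declarative configuration.
# Stage order: preprocess (log transform, purity filter, center/scale) ->
# consensus clustering of pathway genes -> core-cluster selection ->
# quadrant subtype assignment -> survival comparison -> mutation/CNV
# contingency analysis. One master seed; per-stage seeds are derived by
# stage-name hashing so adding a stage never perturbs earlier ones.

.default_config <- function() {
  list(
    seed = 1L,
    preprocess = list(purity_min = 0.30, de_log2fc_min = 1.0,
                      centering = "median", scaling = "sd"),
    consensus = list(k_values = 2:5, reps = 100, p_item = 0.8,
                     p_feature = 1.0, linkage_final = "average", k_main = 4),
    subtyping = list(min_composition = 0.5),
    survival = list(min_months = 1, minprop = 0.1),
    mutation = list(min_probes = 10, mean_thresh = 0.2,
                    panel = default_gene_panel()),
    pan_cancer = list(min_samples = 100, homogeneity_min = 0.75),
    synthetic = list()  # overrides forwarded to cohort_config()
  )
}

.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !key %in% c("panel", "synthetic")) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a table")
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Reads a JSON config file (or takes a list), fills defaults, rejects
#' unknown keys, and range-checks every threshold. An empty file or
#' `NULL` yields all defaults.
#'
#' @param config path to a JSON file, or a (possibly partial) config
#'   list, or NULL.
#' @return normalized config list of class `PipelineConfig`.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list()
    else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (is.list(config)) config
  else stop("config must be a path, a list, or NULL")
  cfg <- .merge_config(.default_config(), user)

  with(cfg$preprocess, {
    if (purity_min < 0 || purity_min > 1)
      stop("config key preprocess.purity_min out of range [0,1]")
    if (de_log2fc_min < 0) stop("preprocess.de_log2fc_min must be >= 0")
  })
  cfg$consensus$k_values <- as.integer(cfg$consensus$k_values)
  if (any(cfg$consensus$k_values < 2L))
    stop("config key consensus.k_values: every k must be >= 2")
  if (cfg$consensus$reps < 1) stop("config key consensus.reps must be >= 1")
  if (cfg$consensus$p_item <= 0 || cfg$consensus$p_item > 1)
    stop("config key consensus.p_item out of range (0,1]")
  if (!cfg$consensus$k_main %in% cfg$consensus$k_values)
    stop("config key consensus.k_main must be among k_values")
  if (cfg$subtyping$min_composition < 0 || cfg$subtyping$min_composition > 1)
    stop("config key subtyping.min_composition out of range [0,1]")
  if (cfg$survival$min_months < 0)
    stop("config key survival.min_months must be >= 0")
  if (cfg$survival$minprop <= 0 || cfg$survival$minprop >= 0.5)
    stop("config key survival.minprop out of range (0,0.5)")
  if (cfg$mutation$min_probes < 0)
    stop("config key mutation.min_probes must be >= 0")
  if (cfg$mutation$mean_thresh < 0)
    stop("config key mutation.mean_thresh must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Classify one cohort into metabolic subtypes
#'
#' The preprocessing + clustering + subtyping core shared by the main
#' pipeline, the pan-cancer loop and the synthetic-recovery tests:
#' log10(TPM+1) transform, strict purity filter, gene-wise median/SD
#' location scaling, consensus clustering of the pathway genes, core
#' cluster selection, median pathway scores, quadrant assignment.
#'
#' @param expr `ExpressionMatrix` (counts, tpm, or log_tpm).
#' @param clinical `ClinicalTable` (used for the purity filter; pass NULL
#'   to skip it).
#' @param gene_sets two [gene_set()]s; default [default_gene_sets()].
#' @param config a `PipelineConfig` (see [validate_config()]).
#' @return list with `expression_centered`, `consensus`, `core`, `calls`
#'   (subtype data.frame), `clinical` (purity-filtered), `purity_report`.
#' @export
classify_cohort <- function(expr, clinical = NULL,
                            gene_sets = default_gene_sets(),
                            config = validate_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (expr$scale_tag %in% c("counts", "tpm")) expr <- tpm_log_transform(expr)
  purity_report <- NULL
  if (!is.null(clinical)) {
    flt <- filter_low_purity(expr, clinical, config$preprocess$purity_min)
    expr <- flt$expression
    clinical <- flt$clinical
    purity_report <- flt$report
  }
  centered <- center_scale_genes(expr, config$preprocess$centering,
                                 config$preprocess$scaling)
  keep <- intersect(gene_ids(centered),
                    c(gene_sets[[1]]$genes, gene_sets[[2]]$genes))
  if (!length(keep)) stop("no pathway genes present in the matrix")
  pathway <- em_subset(centered, genes = keep)
  ccfg <- consensus_config(k_values = config$consensus$k_values,
                           reps = config$consensus$reps,
                           p_item = config$consensus$p_item,
                           p_feature = config$consensus$p_feature,
                           linkage_final = config$consensus$linkage_final,
                           seed = derive_seed(config$seed, "consensus"))
  cons <- consensus_cluster(pathway, ccfg)
  labels <- cons$per_k[[as.character(config$consensus$k_main)]]$labels
  core <- select_core_clusters(labels, gene_sets,
                               config$subtyping$min_composition)
  calls <- assign_subtype(compute_pathway_scores(pathway, core))
  list(expression_centered = centered, consensus = cons, core = core,
       calls = calls, clinical = clinical, purity_report = purity_report)
}

#' Run the full pipeline on a cohort directory
#'
#' Expects the [write_cohort()] layout: `expr.tsv` (TPM), `clinical.tsv`,
#' and optionally `sets.gmt` (else the built-in sets), `mutations.maf`,
#' `segments.seg`, `genes.bed`. Writes all stage artifacts plus a
#' `manifest.json` (inputs, normalized config, seed, package version)
#' to `out_dir`. Reruns with the same inputs and config are byte-identical.
#'
#' @param input_dir cohort directory.
#' @param out_dir output directory (created).
#' @param config anything [validate_config()] accepts.
#' @return list of produced artifacts (invisible file paths in
#'   `$artifacts`, plus the in-memory stage results).
#' @export
run_pipeline <- function(input_dir, out_dir, config = NULL) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(input_dir, f)
  if (!file.exists(p("expr.tsv"))) stop("stage data_io: missing expr.tsv")
  if (!file.exists(p("clinical.tsv"))) stop("stage data_io: missing clinical.tsv")
  expr <- read_expression_tsv(p("expr.tsv"), "tpm")
  clinical <- read_clinical_tsv(p("clinical.tsv"))
  sets <- if (file.exists(p("sets.gmt"))) read_gmt(p("sets.gmt"))
          else default_gene_sets()

  cls <- classify_cohort(expr, clinical, sets, cfg)
  out <- function(f) file.path(out_dir, f)
  write_expression_tsv(cls$expression_centered, out("expr.centered.tsv"))
  .write_tsv(cls$consensus$diagnostics, out("consensus_diagnostics.tsv"))
  for (k in cls$consensus$k_values) {
    lab <- cls$consensus$per_k[[as.character(k)]]$labels
    .write_tsv(data.frame(gene = names(lab), cluster = unname(lab)),
               out(sprintf("labels_k%d.tsv", k)))
  }
  .write_tsv(data.frame(set = c(rep("glycolysis", length(cls$core$gly_core)),
                                rep("cholesterol", length(cls$core$chol_core))),
                        gene = c(cls$core$gly_core, cls$core$chol_core)),
             out("core_clusters.tsv"))
  .write_tsv(cls$calls, out("subtypes.tsv"))

  # survival: strict OS filter, KM per subtype, global 4-group log-rank
  clin <- filter_min_followup(cls$clinical, cfg$survival$min_months)
  clin <- clin[clin$sample_id %in% cls$calls$sample_id, , drop = FALSE]
  sub <- as.character(cls$calls$subtype[match(clin$sample_id,
                                              cls$calls$sample_id)])
  curves <- lapply(split(seq_len(nrow(clin)), sub), function(i)
    km_estimate(clin$os_months[i], clin$os_event[i]))
  km_long <- do.call(rbind, lapply(names(curves), function(g)
    data.frame(subtype = g, time = curves[[g]]$time,
               surv = curves[[g]]$surv, n_risk = curves[[g]]$n_risk,
               n_event = curves[[g]]$n_event)))
  .write_tsv(km_long, out("km_curves.tsv"))
  lr <- NULL
  if (length(unique(sub)) >= 2L && sum(clin$os_event) >= 1) {
    lr <- logrank_test_by(clin$os_months, clin$os_event, sub)
    .write_tsv(data.frame(statistic = lr$statistic, df = lr$df,
                          p_value = lr$p_value), out("logrank.tsv"))
  }

  # mutations (optional inputs)
  contingency <- NULL
  if (file.exists(p("mutations.maf"))) {
    muts <- read_maf_minimal(p("mutations.maf"))
    cnv <- if (file.exists(p("segments.seg")) && file.exists(p("genes.bed")))
      call_cnv_from_segments(read_seg(p("segments.seg")),
                             read_bed(p("genes.bed")),
                             cfg$mutation$min_probes,
                             cfg$mutation$mean_thresh)
    else data.frame(sample_id = character(), gene = character(),
                    direction = character(), source = character())
    panel <- intersect(cfg$mutation$panel,
                       unique(c(muts$gene, cnv$gene)))
    if (length(panel)) {
      mm <- build_mutation_matrix(muts, cnv, cls$calls$sample_id, panel)
      .write_tsv(data.frame(sample_id = rownames(mm$altered), mm$altered,
                            check.names = FALSE),
                 out("mutation_matrix.tsv"))
      contingency <- test_gene_by_subtype(mm, cls$calls,
                                          mc_seed = derive_seed(cfg$seed,
                                                                "mutation"))
      .write_tsv(contingency, out("contingency.tsv"))
    }
  }

  manifest <- list(
    inputs = sort(basename(list.files(input_dir))),
    config = unclass(cfg),
    seed = cfg$seed,
    package = "metabosub",
    version = as.character(utils::packageVersion("metabosub")))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(classification = cls, logrank = lr,
                 contingency = contingency,
                 artifacts = list.files(out_dir, full.names = TRUE)))
}
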