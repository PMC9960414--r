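# Synthetic cohort generator. Produces bulk RNA-seq-shaped cohorts with the
# statistical structure the subtyping analysis assumes: two co-expressed
# pathway gene blocks, four planted metabolic subtypes, subtype-dependent
# exponential survival hazards (quiescent best), and subtype-dependent
# mutation frequencies (TP53 highest overall, CDKN2A most differential).
# Everything is deterministic under the config seed.

#' Canonical metabolic subtype labels, in fixed order
#' @export
metabolic_subtypes <- function()
  c("quiescent", "glycolytic", "cholesterogenic", "mixed")

#' Configuration for a synthetic cohort
#'
#' Defaults encode a cohort shaped like a ~480-patient head-and-neck
#' squamous carcinoma series: subtype proportions 0.36/0.23/0.21/0.20
#' (quiescent largest), 29 glycolysis genes with a 12-gene co-expressed
#' core, 24 cholesterol-biosynthesis genes with a 16-gene core, monthly
#' exponential hazards giving the quiescent arm the longest survival, and
#' per-gene, per-subtype mutation probabilities in which TP53 is the most
#' frequently altered gene and CDKN2A the most subtype-differential.
#'
#' @param n_samples number of samples.
#' @param subtype_proportions length-4 non-negative vector summing to 1, in
#'   the order quiescent, glycolytic, cholesterogenic, mixed.
#' @param n_gly_genes,n_chol_genes pathway set sizes.
#' @param n_core_gly,n_core_chol sizes of the co-expressed (signal) cores.
#' @param effect_size mean shift of an up-regulated core block, in
#'   within-gene SD units, on the log10(TPM+1) scale.
#' @param noise_sd within-gene SD of the log-scale noise.
#' @param baseline_hazards length-4 positive monthly exponential hazards,
#'   subtype order as above.
#' @param censor_rate probability a sample is right-censored uniformly
#'   before its event time.
#' @param mutation_freqs named list: gene -> length-4 probability vector
#'   (subtype order as above).
#' @param purity_range length-2 interval in \[0,1\] for uniform tumor purity.
#' @param n_cnv_spans copy-number spans drawn per sample (amplified /
#'   deleted / neutral, overlapping named genes).
#' @param seed integer RNG seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 480,
                          subtype_proportions = c(0.36, 0.23, 0.21, 0.20),
                          n_gly_genes = 29, n_chol_genes = 24,
                          n_core_gly = 12, n_core_chol = 16,
                          effect_size = 2, noise_sd = 1,
                          baseline_hazards = c(0.010, 0.032, 0.026, 0.030),
                          censor_rate = 0.4,
                          mutation_freqs = default_mutation_freqs(),
                          purity_range = c(0.2, 1.0),
                          n_cnv_spans = 2,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_proportions = as.numeric(subtype_proportions),
              n_gly_genes = as.integer(n_gly_genes),
              n_chol_genes = as.integer(n_chol_genes),
              n_core_gly = as.integer(n_core_gly),
              n_core_chol = as.integer(n_core_chol),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_hazards = as.numeric(baseline_hazards),
              censor_rate = censor_rate,
              mutation_freqs = mutation_freqs,
              purity_range = as.numeric(purity_range),
              n_cnv_spans = as.integer(n_cnv_spans),
              seed = as.integer(seed))
  if (length(cfg$subtype_proportions) != 4L ||
      any(cfg$subtype_proportions < 0) ||
      abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must be 4 non-negative values summing to 1")
  if (cfg$n_samples < 1L) stop("n_samples must be positive")
  if (cfg$n_core_gly > cfg$n_gly_genes || cfg$n_core_chol > cfg$n_chol_genes)
    stop("core sizes cannot exceed set sizes")
  if (any(c(cfg$n_gly_genes, cfg$n_chol_genes,
            cfg$n_core_gly, cfg$n_core_chol) < 1L))
    stop("gene counts must be positive")
  if (cfg$effect_size < 0 || cfg$noise_sd <= 0)
    stop("effect_size must be >= 0 and noise_sd > 0")
  if (length(cfg$baseline_hazards) != 4L ||
      any(!is.finite(cfg$baseline_hazards)) || any(cfg$baseline_hazards <= 0))
    stop("baseline_hazards must be 4 finite positive values")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (length(cfg$purity_range) != 2L || cfg$purity_range[1] > cfg$purity_range[2] ||
      cfg$purity_range[1] < 0 || cfg$purity_range[2] > 1)
    stop("purity_range must be an interval within [0, 1]")
  ok <- vapply(cfg$mutation_freqs, function(p)
    length(p) == 4L && all(p >= 0 & p <= 1), logical(1))
  if (!all(ok)) stop("each mutation_freqs entry needs 4 probabilities")
  class(cfg) <- "cohort_config"
  cfg
}

#' Default per-subtype mutation probabilities for the synthetic cohort
#'
#' TP53 has the highest frequency in every subtype; CDKN2A is the most
#' differential across subtypes; PIK3CA, LRP1B and FLG are intermediate.
#' Order within each vector: quiescent, glycolytic, cholesterogenic, mixed.
#' @return named list of length-4 probability vectors.
#' @export
default_mutation_freqs <- function() {
  list(TP53   = c(0.60, 0.80, 0.75, 0.78),
       CDKN2A = c(0.05, 0.45, 0.15, 0.35),
       PIK3CA = c(0.15, 0.25, 0.20, 0.28),
       LRP1B  = c(0.20, 0.30, 0.22, 0.32),
       FLG    = c(0.20, 0.24, 0.30, 0.26))
}

# lay genes along chromosomes 1..22: 20 kb genes, 1 Mb apart
.make_gene_coords <- function(genes) {
  n <- length(genes)
  chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
  slot <- (seq_len(n) - 1L) %/% 22L
  start <- 1e6 * (slot + 1)
  gene_coordinates(data.frame(gene = genes, chrom = chrom,
                              start = start, end = start + 2e4 - 1,
                              stringsAsFactors = FALSE))
}

# pad a symbol list out to n with synthetic symbols
.take_genes <- function(base, n, prefix) {
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("%s%02d", prefix, seq_len(n - length(base))))
}

#' Generate a synthetic cohort
#'
#' Expression is drawn as Gaussian on the log10(TPM+1) scale and
#' back-transformed to TPM, so the preprocessing log transform is exercised
#' meaningfully. Core glycolytic genes are mean-shifted by
#' `+effect_size * noise_sd` in glycolytic and mixed samples and by the
#' negative of that otherwise; core cholesterogenic genes analogously in
#' cholesterogenic/mixed samples; non-core genes are pure noise. Survival
#' times are exponential with the subtype's hazard; a `censor_rate`
#' fraction of samples is censored uniformly before the event. Mutations
#' are Bernoulli per (gene, subtype); copy-number spans are drawn per
#' sample over named genes so the SEG-to-gene mapping path is testable.
#'
#' @param config a [cohort_config()].
#' @param id_prefix prefix for generated sample ids.
#' @return list of class `SyntheticCohort` with elements `expression`
#'   (TPM `ExpressionMatrix`), `clinical`, `mutations`, `segments`,
#'   `gene_coords`, and `truth` (list with `subtype` data.frame and
#'   `core_genes` flags).
#' @export
generate_cohort <- function(config, id_prefix = "S") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  subtypes <- metabolic_subtypes()
  planted <- sample(subtypes, n, replace = TRUE,
                    prob = config$subtype_proportions)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))

  sets <- default_gene_sets()
  gly_genes <- .take_genes(sets[[1]]$genes, config$n_gly_genes, "GLYX")
  chol_genes <- .take_genes(sets[[2]]$genes, config$n_chol_genes, "CHOLX")
  genes <- c(gly_genes, chol_genes)
  core_gly <- gly_genes[seq_len(config$n_core_gly)]
  core_chol <- chol_genes[seq_len(config$n_core_chol)]

  # log10(TPM+1)-scale means: cores sit higher so the back-transform stays
  # comfortably positive even after a downward shift
  is_core <- genes %in% c(core_gly, core_chol)
  base_mean <- ifelse(is_core, stats::runif(length(genes), 1.8, 2.6),
                      stats::runif(length(genes), 0.8, 2.4))
  shift <- config$effect_size * config$noise_sd
  up_gly <- planted %in% c("glycolytic", "mixed")
  up_chol <- planted %in% c("cholesterogenic", "mixed")
  delta <- matrix(0, length(genes), n, dimnames = list(genes, ids))
  delta[core_gly, ] <- rep(ifelse(up_gly, shift, -shift),
                           each = length(core_gly))
  delta[core_chol, ] <- rep(ifelse(up_chol, shift, -shift),
                            each = length(core_chol))
  logx <- base_mean + delta +
    matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
           length(genes), n)
  tpm <- pmax(10^logx - 1, 0)
  dimnames(tpm) <- list(genes, ids)
  expr <- expression_matrix(tpm, "tpm")

  # survival: exponential event times, uniform censoring for a fixed fraction
  haz <- config$baseline_hazards[match(planted, subtypes)]
  t_event <- stats::rexp(n, rate = haz)
  cens <- stats::runif(n) < config$censor_rate
  os <- ifelse(cens, stats::runif(n, 0, t_event), t_event)
  clin <- clinical_table(data.frame(
    sample_id = ids,
    os_months = os,
    os_event = as.integer(!cens),
    purity = stats::runif(n, config$purity_range[1], config$purity_range[2]),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2)),
    grade = sample(c("G1", "G2", "G3"), n, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25)),
    age = round(stats::rnorm(n, 61, 10)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.7, 0.3)),
    smoking = sample(c("yes", "no"), n, replace = TRUE),
    stringsAsFactors = FALSE))

  coords <- .make_gene_coords(unique(c(genes, names(config$mutation_freqs))))

  # mutations: Bernoulli per (gene, subtype); SNV:INDEL at 4:1
  mut_rows <- list()
  for (g in names(config$mutation_freqs)) {
    p <- config$mutation_freqs[[g]][match(planted, subtypes)]
    hit <- stats::runif(n) < p
    if (!any(hit)) next
    gi <- coords[coords$gene == g, ]
    mut_rows[[g]] <- data.frame(
      sample_id = ids[hit], gene = g,
      variant_class = sample(c("SNV", "INDEL"), sum(hit), replace = TRUE,
                             prob = c(0.8, 0.2)),
      chrom = gi$chrom,
      pos = round(stats::runif(sum(hit), gi$start, gi$end)),
      stringsAsFactors = FALSE)
  }
  muts <- mutation_table(if (length(mut_rows)) do.call(rbind, mut_rows)
                         else data.frame(sample_id = character(),
                                         gene = character(),
                                         variant_class = character(),
                                         chrom = character(),
                                         pos = numeric()))
  rownames(muts) <- NULL

  # copy-number spans over random named genes; some below the probe filter
  n_seg <- n * config$n_cnv_spans
  gi <- coords[sample.int(nrow(coords), n_seg, replace = TRUE), ]
  dir <- sample(c("amp", "del", "neutral"), n_seg, replace = TRUE,
                prob = c(0.35, 0.35, 0.30))
  segm <- ifelse(dir == "amp", stats::runif(n_seg, 0.3, 1.2),
                 ifelse(dir == "del", stats::runif(n_seg, -1.2, -0.3),
                        stats::runif(n_seg, -0.1, 0.1)))
  pad <- round(stats::runif(n_seg, 0, 5e5))
  segs <- segment_table(data.frame(
    sample_id = rep(ids, each = config$n_cnv_spans),
    chrom = gi$chrom,
    start = pmax(1, gi$start - pad),
    end = gi$end + pad,
    num_probes = sample(5:60, n_seg, replace = TRUE),
    seg_mean = segm,
    stringsAsFactors = FALSE))

  truth <- list(
    subtype = data.frame(sample_id = ids, subtype = planted,
                         stringsAsFactors = FALSE),
    core_genes = data.frame(
      gene = genes,
      set = rep(c("glycolysis", "cholesterol"),
                c(length(gly_genes), length(chol_genes))),
      core = genes %in% c(core_gly, core_chol),
      stringsAsFactors = FALSE))

  structure(list(expression = expr, clinical = clin, mutations = muts,
                 segments = segs, gene_coords = coords, truth = truth,
                 config = config),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d samples, %d genes (seed %d)\n",
              ncol(x$expression$values), nrow(x$expression$values),
              x$config$seed))
  print(table(x$truth$subtype$subtype))
  invisible(x)
}

# deterministic 31-bit hash of a string, for deriving per-cohort seeds
.hash_string <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Derive a child seed from a master seed and a label
#' @param seed integer master seed.
#' @param label character tag (e.g. cancer code or stage name).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + .hash_string(label)) %% 2147483647)
}

#' Generate independent cohorts for several cancer types
#'
#' Each cohort gets a seed derived deterministically from its own config
#' seed and the cancer code, and sample ids prefixed with the code so the
#' id universes are disjoint.
#'
#' @param configs named list: cancer code -> [cohort_config()].
#' @return named list of `SyntheticCohort` objects.
#' @export
generate_pan_cancer <- function(configs) {
  if (length(configs) < 1L) stop("need at least one cohort config")
  codes <- names(configs)
  if (is.null(codes) || any(!nzchar(codes)))
    stop("configs must be a named list of cancer codes")
  if (anyDuplicated(codes))
    stop("duplicate cancer code: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  out <- lapply(codes, function(code) {
    cfg <- configs[[code]]
    cfg$seed <- derive_seed(cfg$seed, code)
    generate_cohort(cfg, id_prefix = paste0(code, "-S"))
  })
  names(out) <- codes
  out
}

#' Write all tables of a synthetic cohort to a directory
#'
#' Emits `expr.tsv` (TPM), `clinical.tsv`, `mutations.maf`, `segments.seg`,
#' `genes.bed` and `truth.tsv` in the data-io formats.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expr.tsv"))
  write_clinical_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_maf_minimal(cohort$mutations, file.path(dir, "mutations.maf"))
  write_seg(cohort$segments, file.path(dir, "segments.seg"))
  write_bed(cohort$gene_coords, file.path(dir, "genes.bed"))
  .write_tsv(cohort$truth$subtype, file.path(dir, "truth.tsv"))
  invisible(dir)
}
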