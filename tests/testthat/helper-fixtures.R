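# Shared fixtures and small utilities; everything is built in code.

# two partitions agree up to relabeling
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# planted-block gene matrix: `sizes` genes per block, block means separated
# by `sep`, gaussian noise `noise`; samples carry no structure
block_matrix <- function(sizes, n_samples = 20, sep = 10, noise = 0,
                         seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  centers <- rep(seq_along(sizes) * sep, sizes)
  x <- matrix(rnorm(n * n_samples, mean = centers, sd = noise), n, n_samples)
  dimnames(x) <- list(sprintf("G%02d", seq_len(n)),
                      sprintf("S%02d", seq_len(n_samples)))
  x
}

# tiny clinical table
tiny_clinical <- function(ids, os, ev, purity = NULL) {
  df <- data.frame(sample_id = ids, os_months = os, os_event = ev,
                   stringsAsFactors = FALSE)
  if (!is.null(purity)) df$purity <- purity
  clinical_table(df)
}

# two tiny gene sets for core-selection tests
tiny_sets <- function() list(gene_set("GLY", sprintf("g%02d", 1:10)),
                             gene_set("CHOL", sprintf("c%02d", 1:10)))
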