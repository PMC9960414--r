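test_that("ploidy calls use inclusive thresholds around diploid", {
  cs <- matrix(c(2, 3, 1, 0, 4, 2), 2, 3,
               dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  calls <- call_cnv_from_ploidy(cs)
  get <- function(s, g) calls$direction[calls$sample_id == s & calls$gene == g]
  expect_length(get("S1", "A"), 0)              # status 2: no call
  expect_equal(get("S2", "A"), "amplified")     # 3 inclusive
  expect_equal(get("S1", "B"), "deleted")       # 1 inclusive
  expect_equal(get("S2", "B"), "deleted")       # 0
  expect_equal(get("S1", "C"), "amplified")     # 4
  expect_true(all(calls$source == "ploidy"))
  cs[1] <- -1
  expect_error(call_cnv_from_ploidy(cs), "negative")
})

seg_fix <- function(...) {
  segment_table(data.frame(..., stringsAsFactors = FALSE))
}
coords_fix <- gene_coordinates(data.frame(
  gene = c("TP53", "CDKN2A"), chrom = c("1", "2"),
  start = c(1000, 5000), end = c(1999, 5999), stringsAsFactors = FALSE))

test_that("segment calls: probes inclusive, seg-mean strict, any overlap", {
  segs <- seg_fix(sample_id = c("S1", "S1", "S1", "S1"),
                  chrom = c("1", "1", "1", "2"),
                  start = c(900, 900, 900, 5990),
                  end = c(1100, 1100, 1100, 9000),
                  num_probes = c(12, 50, 9, 10),
                  seg_mean = c(0.25, 0.2, 0.9, -0.21))
  calls <- call_cnv_from_segments(segs, coords_fix)
  # row 1: passes both -> TP53 amplified; row 2: mean == 0.2 fails strict >;
  # row 3: 9 probes fails inclusive >= 10; row 4: 10-bp overlap -> deletion
  expect_equal(nrow(calls), 2)
  expect_equal(calls$direction[calls$gene == "TP53"], "amplified")
  expect_equal(calls$direction[calls$gene == "CDKN2A"], "deleted")

  # exactly min_probes passes; negative strict threshold
  segs2 <- seg_fix(sample_id = "S2", chrom = "1", start = 1, end = 10000,
                   num_probes = 10, seg_mean = -0.2)
  expect_equal(nrow(call_cnv_from_segments(segs2, coords_fix)), 0)
  segs2$seg_mean <- -0.200001
  expect_equal(call_cnv_from_segments(segs2, coords_fix)$direction, "deleted")
})

test_that("segment calls are order- and split-invariant", {
  segs <- seg_fix(sample_id = c("S1", "S2"), chrom = c("1", "2"),
                  start = c(500, 5500), end = c(1500, 6500),
                  num_probes = c(20, 20), seg_mean = c(0.5, -0.5))
  a <- call_cnv_from_segments(segs, coords_fix)
  b <- call_cnv_from_segments(segs[2:1, ], coords_fix)
  expect_equal(a[order(a$sample_id), ], b[order(b$sample_id), ],
               ignore_attr = TRUE)
  # split one event into two adjacent halves with the same mean/probes
  split_segs <- seg_fix(sample_id = c("S1", "S1", "S2"),
                        chrom = c("1", "1", "2"),
                        start = c(500, 1001, 5500), end = c(1000, 1500, 6500),
                        num_probes = c(20, 20, 20),
                        seg_mean = c(0.5, 0.5, -0.5))
  c_ <- unique(call_cnv_from_segments(split_segs, coords_fix))
  expect_equal(c_[order(c_$sample_id), ], a[order(a$sample_id), ],
               ignore_attr = TRUE)
})

test_that("chromosome naming mismatches are rejected", {
  segs <- seg_fix(sample_id = "S1", chrom = "chr1", start = 1, end = 2000,
                  num_probes = 20, seg_mean = 0.5)
  expect_error(call_cnv_from_segments(segs, coords_fix),
               "chromosome naming mismatch")
})

test_that("mutation matrix collapses to binary OR semantics", {
  muts <- mutation_table(data.frame(
    sample_id = c("S1", "S1", "S1", "S2"),
    gene = c("TP53", "TP53", "TP53", "CDKN2A"),
    variant_class = c("SNV", "SNV", "INDEL", "SNV"),
    stringsAsFactors = FALSE))
  cnv <- data.frame(sample_id = "S3", gene = "TP53",
                    direction = "amplified", source = "segment")
  mm <- build_mutation_matrix(muts, cnv, c("S1", "S2", "S3", "S4"),
                              c("TP53", "CDKN2A"))
  expect_equal(mm$snv_indel["S1", "TP53"], 1L)     # 3 records -> 1
  expect_equal(mm$altered["S3", "TP53"], 1L)       # CNV-only alteration
  expect_equal(unname(mm$altered["S4", ]), c(0L, 0L))  # absent -> wild-type
  expect_identical(mm$altered,
                   pmin(mm$snv_indel + mm$amplified + mm$deleted, 1L))
  expect_error(build_mutation_matrix(muts, cnv, "S1", character()),
               "non-empty")
})

test_that("contingency engine matches the textbook chi-square formula", {
  tab <- rbind(altered = c(20, 5, 5, 5), wild = c(30, 45, 45, 45))
  ct <- contingency_test(tab, method = "chi2")
  # independent oracle: direct sum over cells
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:4) {
    e <- rs[i] * cs[j] / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  expect_lt(abs(ct$statistic - stat), 1e-8)
  expect_equal(ct$df, 3)
  expect_equal(ct$p_value, unname(pchisq(stat, 3, lower.tail = FALSE)))

  flat <- rbind(c(10, 10, 10, 10), c(10, 10, 10, 10))
  ct0 <- contingency_test(flat)
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$p_value, 1)

  sparse <- rbind(c(2, 1), c(3, 30))
  cts <- contingency_test(sparse, seed = 1)
  expect_equal(cts$test_used, "fisher")
  expect_identical(contingency_test(sparse, seed = 1)$p_value, cts$p_value)
})

test_that("contingency chi-square is null-calibrated", {
  set.seed(202)
  rej <- mean(replicate(2000, {
    sub <- sample(1:4, 400, TRUE); alt <- rbinom(400, 1, 0.5)
    tab <- rbind(tapply(alt, sub, sum), tapply(1 - alt, sub, sum))
    contingency_test(tab, method = "chi2")$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("test_gene_by_subtype tests the panel with BH correction", {
  co <- generate_cohort(cohort_config(n_samples = 400, seed = 33))
  calls <- data.frame(sample_id = co$truth$subtype$sample_id,
                      subtype = co$truth$subtype$subtype)
  mm <- build_mutation_matrix(co$mutations,
                              data.frame(sample_id = character(),
                                         gene = character(),
                                         direction = character(),
                                         source = character()),
                              calls$sample_id)
  res <- test_gene_by_subtype(mm, calls)
  expect_setequal(res$gene, default_gene_panel())
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # CDKN2A is planted as the most subtype-differential gene
  expect_equal(res$gene[which.max(res$statistic)], "CDKN2A")
  # TP53 planted with the highest overall frequency
  overall <- colMeans(mm$altered)
  expect_equal(names(which.max(overall)), "TP53")
  tabs <- attr(res, "tables")
  expect_equal(sum(tabs[["TP53"]]), nrow(calls))

  one <- calls; one$subtype <- "quiescent"
  expect_error(test_gene_by_subtype(mm, one), "one subtype")
})
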