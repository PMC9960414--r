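test_that("core selection applies the composition and homogeneity rules", {
  sets <- tiny_sets()
  # cluster 1: 8 gly + 2 chol; cluster 2: 2 gly + 8 chol
  labels <- c(stats::setNames(rep(1, 8), sprintf("g%02d", 1:8)),
              stats::setNames(rep(2, 2), sprintf("g%02d", 9:10)),
              stats::setNames(rep(1, 2), sprintf("c%02d", 1:2)),
              stats::setNames(rep(2, 8), sprintf("c%02d", 3:10)))
  core <- select_core_clusters(labels, sets)
  expect_setequal(core$gly_core, sprintf("g%02d", 1:8))
  expect_setequal(core$chol_core, sprintf("c%02d", 3:10))
  expect_equal(unname(core$homogeneity), c(0.8, 0.8))

  # most homogeneous candidate wins over a larger but less pure one
  labels2 <- c(stats::setNames(rep(1, 6), sprintf("g%02d", 1:6)),   # 6/8 gly
               stats::setNames(rep(1, 2), sprintf("c%02d", 1:2)),
               stats::setNames(rep(2, 4), sprintf("g%02d", 7:10)),  # pure gly
               stats::setNames(rep(3, 8), sprintf("c%02d", 3:10)))
  core2 <- select_core_clusters(labels2, sets)
  expect_equal(core2$cluster_gly, 2)
  expect_setequal(core2$gly_core, sprintf("g%02d", 7:10))

  # single all-in-one cluster contested by both sets -> failure
  labels3 <- stats::setNames(rep(1, 20), c(sprintf("g%02d", 1:10),
                                           sprintf("c%02d", 1:10)))
  expect_error(select_core_clusters(labels3, sets), "both sets")

  # no candidate at all for a set -> failure naming the set
  labels3b <- c(stats::setNames(rep(1, 5), sprintf("g%02d", 1:5)),
                stats::setNames(rep(1, 2), sprintf("c%02d", 1:2)),
                stats::setNames(rep(2, 5), sprintf("g%02d", 6:10)),
                stats::setNames(rep(2, 2), sprintf("c%02d", 3:4)))
  expect_error(select_core_clusters(labels3b, sets), "CHOL")

  # gene in neither set
  bad <- c(labels, X1 = 1)
  expect_error(select_core_clusters(bad, sets), "exactly one set")
})

test_that("a 50/50 cluster can serve the set with no other candidate", {
  sets <- tiny_sets()
  # cluster 1 is 5 gly + 5 chol (composition 0.5 for both);
  # cluster 2 is pure chol -> chol has an alternative, gly does not
  labels <- c(stats::setNames(rep(1, 5), sprintf("g%02d", 1:5)),
              stats::setNames(rep(1, 5), sprintf("c%02d", 1:5)),
              stats::setNames(rep(2, 5), sprintf("c%02d", 6:10)),
              stats::setNames(rep(3, 5), sprintf("g%02d", 6:10)))
  # cluster 3 is pure gly, so gly prefers cluster 3; no conflict at all
  core <- select_core_clusters(labels, sets)
  expect_equal(core$cluster_gly, 3)
  expect_equal(core$cluster_chol, 2)

  # now remove the pure-gly cluster: shared 50/50 cluster must go to gly
  labels4 <- c(stats::setNames(rep(1, 5), sprintf("g%02d", 1:5)),
               stats::setNames(rep(1, 5), sprintf("c%02d", 1:5)),
               stats::setNames(rep(2, 5), sprintf("c%02d", 6:10)))
  core4 <- select_core_clusters(labels4, sets[1:2])
  expect_equal(core4$cluster_gly, 1)
  expect_setequal(core4$gly_core, sprintf("g%02d", 1:5))
  expect_equal(core4$cluster_chol, 2)

  # both sets contest a single candidate cluster -> failure
  labels5 <- c(stats::setNames(rep(1, 5), sprintf("g%02d", 1:5)),
               stats::setNames(rep(1, 5), sprintf("c%02d", 1:5)))
  expect_error(select_core_clusters(labels5, sets), "both sets")
})

test_that("core selection is invariant to cluster relabeling", {
  sets <- tiny_sets()
  labels <- c(stats::setNames(rep(1, 8), sprintf("g%02d", 1:8)),
              stats::setNames(rep(2, 2), sprintf("g%02d", 9:10)),
              stats::setNames(rep(1, 2), sprintf("c%02d", 1:2)),
              stats::setNames(rep(2, 8), sprintf("c%02d", 3:10)))
  relab <- c(`1` = 7, `2` = 3)[as.character(labels)]
  names(relab) <- names(labels)
  a <- select_core_clusters(labels, sets)
  b <- select_core_clusters(relab, sets)
  expect_setequal(a$gly_core, b$gly_core)
  expect_setequal(a$chol_core, b$chol_core)
  expect_equal(a$homogeneity, b$homogeneity)
})

test_that("pathway scores are per-sample medians over the cores", {
  v <- rbind(g1 = c(-1, 5), g2 = c(0, 5), g3 = c(2, 5),
             c1 = c(3, 0), c2 = c(4, 0))
  colnames(v) <- c("A", "B")
  em <- expression_matrix(v, "centered")
  core <- structure(list(gly_core = c("g1", "g2", "g3"),
                         chol_core = c("c1", "c2")),
                    class = "CoreClusters")
  sc <- compute_pathway_scores(em, core)
  expect_equal(sc$gly_score[sc$sample_id == "A"], 0)   # median(-1, 0, 2)
  expect_equal(sc$chol_score[sc$sample_id == "A"], 3.5)
  expect_equal(sc$gly_score[sc$sample_id == "B"], 5)

  core2 <- structure(list(gly_core = "g1", chol_core = "c1"),
                     class = "CoreClusters")
  sc2 <- compute_pathway_scores(em, core2)
  expect_equal(sc2$gly_score, unname(v["g1", ]))  # single-gene core

  core3 <- structure(list(gly_core = "gX", chol_core = "c1"),
                     class = "CoreClusters")
  expect_error(compute_pathway_scores(em, core3), "gX")
})

test_that("quadrant rule puts 0 on the quiescent side", {
  sc <- data.frame(sample_id = paste0("S", 1:4),
                   gly_score = c(0, 1e-9, -0.5, 0.2),
                   chol_score = c(0, 0, 0.3, 0.3))
  out <- assign_subtype(sc)
  expect_equal(as.character(out$subtype),
               c("quiescent", "glycolytic", "cholesterogenic", "mixed"))
  sc$gly_score[1] <- NaN
  expect_error(assign_subtype(sc), "finite")
})

test_that("cross_tabulate recovers identical labelings and degenerates", {
  calls <- assign_subtype(data.frame(
    sample_id = paste0("S", 1:8),
    gly_score = c(-1, -1, 1, 1, -1, -1, 1, 1),
    chol_score = c(-1, -1, -1, -1, 1, 1, 1, 1)))
  ext <- stats::setNames(as.character(calls$subtype), calls$sample_id)
  ct <- cross_tabulate(calls, ext)
  expect_equal(sum(diag(ct$table[, metabolic_subtypes()])), 8)

  one_class <- stats::setNames(rep("only", 8), calls$sample_id)
  expect_warning(ct2 <- cross_tabulate(calls, one_class), "degenerate")
  expect_null(ct2$test)
  expect_error(cross_tabulate(calls, c(ZZ = "x")), "no overlapping")
})

test_that("cross_tabulate chi-square is null-calibrated on random labels", {
  set.seed(31)
  ps <- replicate(300, {
    n <- 400
    calls <- data.frame(sample_id = paste0("S", seq_len(n)),
                        gly_score = rnorm(n), chol_score = rnorm(n))
    calls <- assign_subtype(calls)
    ext <- stats::setNames(sample(letters[1:3], n, TRUE), calls$sample_id)
    cross_tabulate(calls, ext)$test$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})
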