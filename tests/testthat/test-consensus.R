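test_that("noiseless duplicated blocks give a {0,1} consensus matrix", {
  x <- block_matrix(c(5, 5), n_samples = 12, sep = 20, noise = 0)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = 2, reps = 20,
                                                p_item = 1, seed = 4))
  M <- res$per_k[["2"]]$consensus_matrix
  expect_true(all(M %in% c(0, 1)))
  blocks <- rep(1:2, each = 5)
  expect_equal(unname(M[1, ]), as.numeric(blocks == 1))
  expect_true(same_partition(res$per_k[["2"]]$labels, blocks))
})

test_that("a single rep at p_item = 1 yields exactly binary entries", {
  x <- block_matrix(c(4, 4, 4), n_samples = 10, sep = 5, noise = 1, seed = 2)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = c(2, 3), reps = 1,
                                                p_item = 1, seed = 1))
  for (k in c("2", "3"))
    expect_true(all(res$per_k[[k]]$consensus_matrix %in% c(0, 1)))
})

test_that("p_item = 1 reproduces the full-data Ward cut at every k", {
  x <- block_matrix(c(4, 4, 4), n_samples = 15, sep = 6, noise = 1, seed = 3)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = 2:5, reps = 10,
                                                p_item = 1, seed = 2))
  hc <- hclust(dist(x), method = "ward.D2")
  for (k in 2:5)
    expect_true(same_partition(res$per_k[[as.character(k)]]$labels,
                               cutree(hc, k)))
})

test_that("subsampled consensus recovers planted blocks (Ward oracle)", {
  # 12-gene planted 3-block data; oracle = direct full-data Ward cut
  x <- block_matrix(c(4, 4, 4), n_samples = 20, sep = 8, noise = 1, seed = 7)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = 3, reps = 100,
                                                p_item = 0.8, seed = 7))
  oracle <- cutree(hclust(dist(x), method = "ward.D2"), 3)
  expect_true(same_partition(res$per_k[["3"]]$labels, oracle))
})

test_that("consensus matrix is stable under item permutation", {
  x <- block_matrix(c(4, 4), n_samples = 15, sep = 6, noise = 1, seed = 5)
  em <- expression_matrix(x, "centered")
  cfg <- consensus_config(k_values = 2, reps = 100, p_item = 0.8, seed = 6)
  M1 <- consensus_cluster(em, cfg)$per_k[["2"]]$consensus_matrix
  set.seed(99); perm <- sample(nrow(x))
  em2 <- expression_matrix(x[perm, ], "centered")
  M2 <- consensus_cluster(em2, cfg)$per_k[["2"]]$consensus_matrix
  M2 <- M2[rownames(M1), rownames(M1)]
  expect_lt(max(abs(M1 - M2)), 3 / sqrt(100))
})

test_that("more reps do not change planted-block labels on noiseless data", {
  x <- block_matrix(c(5, 5), n_samples = 10, sep = 20, noise = 0)
  em <- expression_matrix(x, "centered")
  l100 <- consensus_cluster(em, consensus_config(k_values = 2, reps = 100,
                                                 seed = 1))$per_k[["2"]]$labels
  l1000 <- consensus_cluster(em, consensus_config(k_values = 2, reps = 1000,
                                                  seed = 1))$per_k[["2"]]$labels
  expect_true(same_partition(l100, l1000))
})

test_that("consensus matrix invariants hold on a noisy run", {
  x <- block_matrix(c(4, 4, 4), n_samples = 12, sep = 3, noise = 2, seed = 9)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = 2:4, reps = 50,
                                                seed = 3))
  for (k in names(res$per_k)) {
    M <- res$per_k[[k]]$consensus_matrix
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, nrow(M)))
    expect_true(all(M >= 0 & M <= 1))
    lab <- res$per_k[[k]]$labels
    expect_setequal(unique(lab), seq_len(as.integer(k)))
  }
})

test_that("degenerate and undersized inputs error", {
  x <- matrix(1, 4, 6, dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  em <- expression_matrix(x, "centered")
  expect_error(consensus_cluster(em, consensus_config(k_values = 2)),
               "identical")
  x2 <- block_matrix(c(2, 2), n_samples = 6)
  expect_error(consensus_cluster(expression_matrix(x2, "centered"),
                                 consensus_config(k_values = 4)),
               "at least")
  expect_error(consensus_config(k_values = 1), ">= 2")
  expect_error(consensus_config(reps = 0), "reps")
  expect_error(consensus_config(p_item = 0), "p_item")
})

test_that("cdf_delta_area matches the closed-form ECDF integral", {
  # oracle: integral over [0,1] of the ECDF of v equals 1 - mean(v)
  x <- block_matrix(c(4, 4, 4), n_samples = 12, sep = 3, noise = 1.5, seed = 13)
  em <- expression_matrix(x, "centered")
  res <- consensus_cluster(em, consensus_config(k_values = 2:5, reps = 60,
                                                seed = 13))
  d <- cdf_delta_area(res)
  for (i in seq_along(res$k_values)) {
    M <- res$per_k[[i]]$consensus_matrix
    v <- M[upper.tri(M)]
    expect_equal(d$auc[i], 1 - mean(v), tolerance = 1e-10)
  }
  # delta_area definition: first k -> auc; later ks -> relative change
  expect_equal(d$delta_area[1], d$auc[1])
  expect_equal(d$delta_area[-1], diff(d$auc) / d$auc[-nrow(d)],
               tolerance = 1e-12)

  # all-{0,1} consensus: auc = fraction of zero pairs
  x01 <- block_matrix(c(5, 5), n_samples = 10, sep = 20, noise = 0)
  r01 <- consensus_cluster(expression_matrix(x01, "centered"),
                           consensus_config(k_values = 2, reps = 10,
                                            p_item = 1, seed = 1))
  M <- r01$per_k[["2"]]$consensus_matrix
  v <- M[upper.tri(M)]
  expect_equal(r01$diagnostics$auc, mean(v == 0))
})
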