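test_that("flat cuts behave on degenerate panels", {
  two <- tibble::tibble(clone_id = c("a", "b"), v1 = c(0, 5), v2 = c(1, 9))
  res <- cluster_clones(two, k = 2)
  expect_identical(sort(unique(res$labels$cluster)), c(1L, 2L))
  expect_identical(length(unique(res$labels$cluster)), 2L)

  # duplicate clones merge first, at height zero
  dup <- tibble::tibble(clone_id = c("a", "b", "c"),
                        v1 = c(1, 1, 8), v2 = c(2, 2, 9))
  r2 <- cluster_clones(dup, k = 2)
  expect_equal(min(r2$hclust$height), 0)
  expect_identical(r2$labels$cluster[1], r2$labels$cluster[2])

  expect_error(cluster_clones(two, k = 5), "exceeds")
})

test_that("planted regimes are recovered perfectly at 4x separation", {
  panel <- nested_clone_panel(n_per = 20, separation = 4, seed = 77,
                              n_vars = 6)
  # single-stage k = 3 on one superclass worth of structure
  sub <- panel$vectors[panel$super == 1, ]
  res <- cluster_clones(sub, k = 3)
  truth <- panel$sub[panel$super == 1]
  expect_equal(adjusted_rand_index(res$labels$cluster, truth), 1)
})

test_that("two-stage clustering recovers the nested planted hierarchy", {
  panel <- nested_clone_panel(n_per = 10, separation = 4, seed = 42)
  ts <- two_stage_clustering(panel$vectors,
                             superclass_labels = panel$super)
  expect_equal(adjusted_rand_index(ts$labels$superclass, panel$super), 1)
  expect_equal(adjusted_rand_index(ts$labels$subclass_global, panel$sub), 1)
  expect_equal(ts$superclass_agreement, 1)
  # all clones identical: degenerate, no valid cut
  same <- tibble::tibble(clone_id = letters[1:8], v1 = 1, v2 = 2)
  expect_error(suppressWarnings(two_stage_clustering(same)))
})

test_that("clustering is invariant to clone order and variable rescaling", {
  panel <- nested_clone_panel(n_per = 8, separation = 4, seed = 7)
  res <- cluster_clones(panel$vectors, k = 3)
  perm <- sample(nrow(panel$vectors))
  res_perm <- cluster_clones(panel$vectors[perm, ], k = 3)
  m1 <- res$labels$cluster[match(res$labels$clone_id,
                                 res$labels$clone_id)]
  m2 <- res_perm$labels$cluster[match(res$labels$clone_id,
                                      res_perm$labels$clone_id)]
  expect_equal(adjusted_rand_index(m1, m2), 1)
  # affine rescaling of one variable is absorbed by z-scoring
  scaled <- panel$vectors
  scaled$v1 <- scaled$v1 * 1000 - 77
  res_scaled <- cluster_clones(scaled, k = 3)
  expect_equal(adjusted_rand_index(res$labels$cluster,
                                   res_scaled$labels$cluster), 1)
})

test_that("cutting at k then merging the closest pair equals cutting at k-1", {
  panel <- nested_clone_panel(n_per = 6, separation = 3, seed = 11)
  res4 <- cluster_clones(panel$vectors, k = 4)
  res3 <- cluster_clones(panel$vectors, k = 3)
  # the k=3 cut merges exactly two of the k=4 clusters
  tab <- table(res4$labels$cluster, res3$labels$cluster)
  expect_identical(sum(tab > 0), 4L)
  merged <- apply(tab > 0, 2, sum)
  expect_setequal(as.integer(merged), c(1L, 1L, 2L))
})

test_that("constant variables are dropped with a warning", {
  panel <- nested_clone_panel(n_per = 5, separation = 4, seed = 3)
  panel$vectors$flat <- 1.0
  expect_warning(res <- cluster_clones(panel$vectors, k = 2), "constant")
  expect_false("flat" %in% res$variables)
})

test_that("embedding is deterministic and collapses identical vectors", {
  panel <- nested_clone_panel(n_per = 8, separation = 4, seed = 21)
  e1 <- embed_clones(panel$vectors)
  e2 <- embed_clones(panel$vectors)
  expect_identical(e1, e2)
  # planted clusters separate in the embedding
  truth <- panel$sub
  d <- as.matrix(stats::dist(cbind(e1$dim1, e1$dim2)))
  sil <- sapply(seq_len(nrow(d)), function(i) {
    a <- mean(d[i, truth == truth[i] & seq_along(truth) != i])
    b <- min(sapply(setdiff(unique(truth), truth[i]),
                    function(g) mean(d[i, truth == g])))
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)

  dup <- tibble::tibble(clone_id = letters[1:5],
                        v1 = c(1, 1, 5, 5, 9), v2 = c(2, 2, 7, 7, 4))
  ed <- embed_clones(dup)
  expect_lt(abs(ed$dim1[1] - ed$dim1[2]), 1e-9)
  expect_lt(abs(ed$dim2[1] - ed$dim2[2]), 1e-9)
  expect_error(embed_clones(dup[1:3, ]), ">= 4")
})

test_that("agreement with known superclass labels is reported", {
  panel <- nested_clone_panel(n_per = 10, separation = 4, seed = 55)
  ts <- two_stage_clustering(panel$vectors, superclass_labels = panel$super)
  expect_equal(ts$superclass_agreement, 1)
  g <- glance(ts$superclasses)
  expect_identical(g$k, 2L)
  expect_identical(g$n_clones, nrow(panel$vectors))
})
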