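test_that("spearman correlation honours rank structure and ties", {
  x <- 1:10
  tab <- data.frame(a = x, b = x^3, c = -x + 0.0)
  r <- spearman_matrix(tab)
  expect_equal(r["a", "b"], 1)   # monotone transform invariance
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  # 10-clone fixture with ties vs the rank-then-Pearson oracle
  set.seed(41)
  tab2 <- data.frame(u = sample(c(1, 1, 2, 3, 3, 4, 5, 6, 6, 7)),
                     v = rnorm(10), w = rpois(10, 3) + 0.0)
  r2 <- spearman_matrix(tab2)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(r2[i, j], oracle_spearman(tab2[[i]], tab2[[j]]),
                 tolerance = 1e-12)
  }

  # constant variables yield missing correlations
  tab3 <- data.frame(a = x, k = rep(2, 10))
  r3 <- spearman_matrix(tab3)
  expect_true(is.na(r3["a", "k"]))
  expect_equal(r3["k", "k"], 1)
  expect_error(spearman_matrix(data.frame(a = 1:2, b = 2:1)), ">= 3")
})

test_that("correlation graphs honour the strict magnitude threshold", {
  r <- diag(3)
  dimnames(r) <- list(c("x", "y", "z"), c("x", "y", "z"))
  r["x", "y"] <- r["y", "x"] <- 0.85
  r["x", "z"] <- r["z", "x"] <- -0.75
  g <- correlation_graph(r, threshold = 0.8)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$from, "x")
  expect_identical(g$edges$to, "y")
  expect_identical(g$edges$sign, "positive")
  # identity matrix: no edges
  id <- diag(4)
  dimnames(id) <- list(letters[1:4], letters[1:4])
  expect_identical(nrow(correlation_graph(id, 0.8)$edges), 0L)
  # edge sets shrink monotonically with the threshold
  g03 <- correlation_graph(r, threshold = 0.3)
  expect_true(all(paste(g$edges$from, g$edges$to) %in%
                    paste(g03$edges$from, g03$edges$to)))
  # negative edge present at the lower threshold, dashed sign recorded
  expect_setequal(g03$edges$sign, c("positive", "negative"))
})

test_that("invasion correlation graph is a star around invasion3D", {
  set.seed(4)
  n <- 12
  inv <- runif(n)
  tab <- data.frame(clone_id = sprintf("c%02d", 1:n),
                    mono = inv^2 + 1,        # monotone in invasion3D
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    invasion3D = inv)
  g <- invasion_correlations(tab, threshold = 0.3)
  expect_true(all(g$edges$from == "invasion3D" |
                    g$edges$to == "invasion3D"))
  mono_edge <- g$edges[g$edges$from == "mono" | g$edges$to == "mono", ]
  expect_equal(mono_edge$r, 1)
  # 2D-2D relations are never drawn even when strongly correlated
  tab$mono2 <- tab$mono * 2
  g2 <- invasion_correlations(tab, threshold = 0.3)
  expect_false(any(g2$edges$from != "invasion3D" &
                     g2$edges$to != "invasion3D"))
  expect_error(invasion_correlations(tab[, 1:3]), "invasion3D")
})

test_that("null 2D variables connect to invasion3D at the base rate", {
  # the absence rate of a spurious |r| > 0.3 edge at n = 10 clones matches
  # the Spearman null distribution, estimated by an independent
  # rank-then-Pearson Monte-Carlo under the same seeds
  n <- 10
  absent_impl <- logical(200)
  r_oracle <- numeric(200)
  for (i in 1:200) {
    set.seed(5000 + i)
    tab <- data.frame(noise = rnorm(n), invasion3D = runif(n))
    g <- invasion_correlations(tab, threshold = 0.3)
    absent_impl[i] <- nrow(g$edges) == 0L
    r_oracle[i] <- oracle_spearman(tab$noise, tab$invasion3D)
  }
  absent_oracle <- abs(r_oracle) <= 0.3
  expect_identical(absent_impl, absent_oracle)
  expect_gt(mean(absent_impl), 0.5)
})

test_that("variable groups label correlation-graph nodes", {
  groups <- variable_groups(network2D = c("mean_degree_m"),
                            singlecell2D = c("area_um2_mean_m"),
                            dissemination3D = c("n_c"))
  r <- diag(3)
  dimnames(r) <- list(names(groups), names(groups))
  r[1, 2] <- r[2, 1] <- 0.9
  g <- correlation_graph(r, threshold = 0.8, groups = groups)
  expect_identical(g$nodes$group,
                   c("network2D", "singlecell2D", "dissemination3D"))
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 3)
  expect_equal(igraph::ecount(ig), 1)
  expect_error(variable_groups(network2D = "x", singlecell2D = "x"),
               "disjoint")
})
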