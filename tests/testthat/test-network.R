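test_that("adjacency threshold is strict at 5 um on boundary-gap fixtures", {
  # discs radius 20 um, centres 43 um apart: boundary gap ~3 um -> edge
  near <- build_network(two_disc_image(20, 43))
  expect_equal(igraph::ecount(near$graph), 1)
  # centres 50 um apart: gap ~10 um -> no edge
  far <- build_network(two_disc_image(20, 50))
  expect_equal(igraph::ecount(far$graph), 0)
  # discs whose boundary gap is exactly 5 um: strict comparison excludes
  expect_equal(igraph::ecount(build_network(two_disc_image(20, 45))$graph), 0)
  # axis-aligned squares with boundary-pixel distance exactly 5: excluded
  at5 <- rect_image(list(c(10, 19, 5, 14), c(10, 19, 19, 28)), 30, 40)
  expect_equal(igraph::ecount(build_network(at5)$graph), 0)
  at4 <- rect_image(list(c(10, 19, 5, 14), c(10, 19, 18, 27)), 30, 40)
  expect_equal(igraph::ecount(build_network(at4)$graph), 1)
})

test_that("edge set equals planted adjacency and grows with the threshold", {
  pop <- generate_population(synthetic_population_spec(60, 0.4, seed = 17))
  net <- build_network(pop$image)
  el <- apply(igraph::as_edgelist(net$graph), 2, as.integer)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  want <- sort(paste(pop$adjacency$from, pop$adjacency$to))
  expect_identical(got, want)
  # monotone non-decreasing edge set in the threshold
  wider <- build_network(pop$image, adjacency_threshold = 12)
  el2 <- apply(igraph::as_edgelist(wider$graph), 2, as.integer)
  got2 <- paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2]))
  expect_true(all(got %in% got2))
})

test_that("degree statistics match closed forms and the brute-force oracle", {
  p3 <- cell_network_from_edges(3, rbind(c(1, 2), c(2, 3)))
  s <- degree_statistics(p3)
  expect_equal(s$mean_degree, 4 / 3)
  expect_equal(s$degree_variance, 2 / 9)
  expect_equal(s$degree_entropy, -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3))

  edgeless <- cell_network_from_edges(7)
  expect_equal(unlist(degree_statistics(edgeless)), c(mean_degree = 0,
               degree_variance = 0, degree_entropy = 0))
  expect_error(degree_statistics(cell_network_from_edges(0)), "empty")

  set.seed(23)
  adj <- random_adjacency(30, 0.15)
  s2 <- degree_statistics(adjacency_to_network(adj))
  o <- oracle_degree_stats(adj)
  expect_equal(s2$mean_degree, o$mean)
  expect_equal(s2$degree_variance, o$var)
  expect_equal(s2$degree_entropy, o$entropy)
})

test_that("average colorability averages exact chromatic numbers", {
  expect_equal(as.numeric(average_colorability(cell_network_from_edges(1))), 1)
  k3 <- rbind(c(1, 2), c(1, 3), c(2, 3))
  expect_equal(as.numeric(average_colorability(
    cell_network_from_edges(3, k3))), 3)
  # K3 plus K2: (3 + 2) / 2
  expect_equal(as.numeric(average_colorability(
    cell_network_from_edges(5, rbind(k3, c(4, 5))))), 2.5)
  # odd cycle needs 3 colours
  c5 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
  expect_equal(as.numeric(average_colorability(
    cell_network_from_edges(5, c5))), 3)
  # above the exact limit the greedy bound is flagged
  set.seed(1)
  big <- adjacency_to_network(random_adjacency(30, 0.2))
  expect_warning(res <- average_colorability(big, exact_limit = 10),
                 "upper bound")
  expect_false(all(attr(res, "exact")))
})

test_that("topology metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:120) {
    n <- sample(1:12, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.1, 0.7))
    net <- adjacency_to_network(adj)
    o <- oracle_degree_stats(adj)
    s <- degree_statistics(net)
    expect_equal(s$mean_degree, o$mean)
    expect_equal(s$degree_variance, o$var)
    expect_equal(s$degree_entropy, o$entropy)

    sizes <- oracle_components(adj)
    cs <- component_statistics(net)
    expect_equal(cs$n_components, length(sizes))
    expect_equal(cs$largest_component_fraction, max(sizes) / n)
    p <- sizes / n
    expect_equal(cs$component_mass_entropy, -sum(p * log(p)))
    expect_equal(sum(sizes), n)  # masses conserve node count

    chi <- chromatic_number(adj)
    expect_identical(chi, oracle_chromatic(adj))
    # clique lower bound and greedy upper bound bracket chi
    expect_lte(chi, max(rowSums(adj)) + 1)
  }
})

test_that("component statistics have their closed-form fixture values", {
  con <- cell_network_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  cs <- component_statistics(con)
  expect_equal(cs$largest_component_fraction, 1)
  expect_equal(cs$component_mass_entropy, 0)
  # components of sizes 6 and 2
  e6 <- cbind(1:5, 2:6)
  cs2 <- component_statistics(cell_network_from_edges(8, rbind(e6, c(7, 8))))
  expect_equal(cs2$largest_component_fraction, 0.75)
  expect_equal(cs2$component_mass_entropy,
               -0.75 * log(0.75) - 0.25 * log(0.25))
  # equal masses (4, 4) -> ln 2
  cs3 <- component_statistics(
    cell_network_from_edges(8, rbind(cbind(1:3, 2:4), cbind(5:7, 6:8))))
  expect_equal(cs3$component_mass_entropy, log(2))
})

test_that("box-counting dimension recovers known analytic dimensions", {
  expect_equal(as.numeric(fractal_dimension(matrix(1L, 128, 128))), 2,
               tolerance = 0.05 / 2)
  line <- matrix(0L, 128, 128)
  line[64, ] <- 1L
  expect_equal(as.numeric(fractal_dimension(line)), 1, tolerance = 0.05)
  carpet <- sierpinski_carpet(4)
  expect_equal(as.numeric(fractal_dimension(carpet, box_sizes = 3^(0:3))),
               log(8) / log(3), tolerance = 0.05 / 1.9)
  expect_error(fractal_dimension(matrix(0L, 32, 32)), "empty")
  expect_error(fractal_dimension(matrix(1L, 32, 32), box_sizes = c(2, 4)),
               "at least 4")
})

test_that("box-counting is invariant to whole-box translations", {
  carpet <- sierpinski_carpet(3)  # 27 x 27
  pad <- matrix(0L, 54, 54)
  pad[1:27, 1:27] <- carpet
  shifted <- matrix(0L, 54, 54)
  shifted[28:54, 28:54] <- carpet  # translated by 27 = 27 whole 3/9-boxes
  sizes <- c(1, 3, 9, 27)
  expect_equal(as.numeric(fractal_dimension(pad, box_sizes = sizes)),
               as.numeric(fractal_dimension(shifted, box_sizes = sizes)),
               tolerance = 1e-9)
})
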