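#' Build the cell adjacency network of a label image
#'
#' Nodes are segmented cells; an edge joins two cells whose minimum
#' edge-to-edge (boundary pixel centre to boundary pixel centre, Euclidean,
#' micrometres) distance is strictly below `adjacency_threshold`
#' (default 5 um). Border-touching cells are kept as nodes: truncated
#' shapes bias morphology but still occupy topology.
#'
#' Candidate pairs are pruned by bounding-box separation before exact
#' boundary-pixel distances are computed, so the result is identical to the
#' brute-force all-pairs computation.
#'
#' @param img A [label_image()].
#' @param adjacency_threshold Edge threshold in micrometres (> 0); the
#'   comparison is strict, so a gap of exactly the threshold yields no edge.
#' @return An object of class `cell_network` wrapping an igraph graph with
#'   vertex attributes `name` (cell id), `x_um`, `y_um`, `area_um2`,
#'   `on_border`.
#' @export
build_network <- function(img, adjacency_threshold = 5) {
  stopifnot(inherits(img, "label_image"), adjacency_threshold > 0)
  px <- img$pixels
  ps <- img$pixel_size
  k <- max(px)
  cells <- measure_cells(img)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (k > 0L) {
    igraph::V(g)$name <- as.character(cells$cell_id)
    igraph::V(g)$x_um <- cells$x_um
    igraph::V(g)$y_um <- cells$y_um
    igraph::V(g)$area_um2 <- cells$area_um2
    igraph::V(g)$on_border <- cells$on_border
  }
  if (k >= 2L) {
    bnd <- boundary_pixels(px, k)
    thr_px <- adjacency_threshold / ps
    # bounding boxes in pixel units
    bb <- t(vapply(bnd, function(b) {
      c(min(b[, 1]), max(b[, 1]), min(b[, 2]), max(b[, 2]))
    }, numeric(4)))
    edges <- integer(0)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dr <- max(0, max(bb[i, 1], bb[j, 1]) - min(bb[i, 2], bb[j, 2]))
        dc <- max(0, max(bb[i, 3], bb[j, 3]) - min(bb[i, 4], bb[j, 4]))
        if (sqrt(dr^2 + dc^2) >= thr_px) next
        if (min_boundary_dist(bnd[[i]], bnd[[j]]) < thr_px) {
          edges <- c(edges, i, j)
        }
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  new_cell_network(g)
}

# boundary pixels (row, col matrix) per label: pixels with a 4-neighbour
# outside the label (or on the image edge)
boundary_pixels <- function(px, k) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_bnd <- core > 0L & (
    pad[1:nr, 2:(nc + 1L)] != core | pad[3:(nr + 2L), 2:(nc + 1L)] != core |
    pad[2:(nr + 1L), 1:nc] != core | pad[2:(nr + 1L), 3:(nc + 2L)] != core
  )
  idx <- which(is_bnd)
  lab <- core[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  lapply(seq_len(k), function(l) {
    sel <- lab == l
    cbind(rows[sel], cols[sel])
  })
}

# exact minimum Euclidean distance (px) between two boundary pixel sets,
# chunked to bound memory
min_boundary_dist <- function(a, b, chunk = 4096L) {
  best <- Inf
  nb <- nrow(b)
  for (s in seq(1L, nb, by = chunk)) {
    e <- min(nb, s + chunk - 1L)
    d2 <- outer(a[, 1], b[s:e, 1], "-")^2 + outer(a[, 2], b[s:e, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

new_cell_network <- function(g) {
  structure(list(graph = g), class = "cell_network")
}

#' Construct a cell network from an explicit edge list
#'
#' Mainly for testing and for graphs imported from elsewhere.
#'
#' @param n_nodes Node count.
#' @param edges Two-column matrix (or empty) of 1-based node index pairs.
#' @return A `cell_network`.
#' @export
cell_network_from_edges <- function(n_nodes, edges = NULL) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (n_nodes > 0L) igraph::V(g)$name <- as.character(seq_len(n_nodes))
  if (!is.null(edges) && length(edges)) {
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  }
  new_cell_network(igraph::simplify(g))
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("<cell_network> %d nodes, %d edges, %d components\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              igraph::count_components(x$graph)))
  invisible(x)
}

#' Degree statistics of a cell network
#'
#' Mean, population variance and Shannon entropy (natural log, exact
#' integer-degree bins) of the vertex degree sequence; together they
#' describe the likelihood of cell-cell adjacencies.
#'
#' @param net A `cell_network`.
#' @return A one-row tibble: `mean_degree`, `degree_variance`,
#'   `degree_entropy`.
#' @export
degree_statistics <- function(net) {
  stopifnot(inherits(net, "cell_network"))
  deg <- igraph::degree(net$graph)
  if (!length(deg)) stop("degree_statistics: empty network")
  tibble::tibble(
    mean_degree = mean(deg),
    degree_variance = pop_var(deg),
    degree_entropy = shannon_entropy(deg, bins = "exact")
  )
}

#' Average colorability of a cell network
#'
#' The chromatic number of each connected component, averaged over
#' components: a proxy for the maximum achievable packing density of cells.
#' Components with at most `exact_limit` nodes are solved exactly by
#' backtracking; larger components fall back to a greedy (largest-first)
#' upper bound and the result is flagged as an upper bound.
#'
#' @param net A `cell_network` with at least one node.
#' @param exact_limit Largest component size solved exactly (default 20;
#'   chromatic number is NP-hard in general, but cell adjacency components
#'   are small and near-planar).
#' @return Mean chromatic number (numeric scalar) with attributes
#'   `chi` (per-component values) and `exact` (per-component logical;
#'   FALSE marks greedy upper bounds).
#' @export
average_colorability <- function(net, exact_limit = 20L) {
  stopifnot(inherits(net, "cell_network"))
  if (igraph::vcount(net$graph) == 0L) stop("average_colorability: empty network")
  comps <- igraph::decompose(net$graph)
  chi <- numeric(length(comps))
  exact <- logical(length(comps))
  for (i in seq_along(comps)) {
    adj <- as.matrix(igraph::as_adjacency_matrix(comps[[i]], sparse = FALSE))
    if (nrow(adj) <= exact_limit) {
      chi[i] <- chromatic_number(adj)
      exact[i] <- TRUE
    } else {
      chi[i] <- max(greedy_coloring(adj))
      exact[i] <- FALSE
    }
  }
  if (!all(exact)) {
    warning(sum(!exact), " component(s) exceeded exact_limit; ",
            "greedy upper bound used")
  }
  structure(mean(chi), chi = chi, exact = exact)
}

#' Exact chromatic number of a small graph by backtracking
#'
#' Iterative deepening: for k = lower bound (greedy clique) upward, a
#' backtracking search decides k-colorability, visiting vertices in
#' descending degree order and breaking colour symmetry by allowing at most
#' one previously unused colour per step.
#'
#' @param adj Symmetric 0/1 adjacency matrix, zero diagonal.
#' @return The chromatic number (integer).
#' @export
chromatic_number <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  if (sum(adj) == 0) return(1L)
  ub <- max(greedy_coloring(adj))
  lb <- greedy_clique_size(adj)
  for (k in lb:ub) {
    if (k == ub || k_colorable(adj, k)) return(as.integer(k))
  }
  as.integer(ub)
}

# greedy largest-first proper coloring; returns colour per vertex
greedy_coloring <- function(adj) {
  n <- nrow(adj)
  ord <- order(rowSums(adj), decreasing = TRUE)
  col <- integer(n)
  for (v in ord) {
    used <- col[adj[v, ] > 0]
    c <- 1L
    while (c %in% used) c <- c + 1L
    col[v] <- c
  }
  col
}

# greedy clique (lower bound for chi): grow from highest-degree vertex
greedy_clique_size <- function(adj) {
  n <- nrow(adj)
  ord <- order(rowSums(adj), decreasing = TRUE)
  clique <- integer(0)
  for (v in ord) {
    if (all(adj[v, clique] > 0)) clique <- c(clique, v)
  }
  max(1L, length(clique))
}

# backtracking k-colorability, vertices in descending degree order
k_colorable <- function(adj, k) {
  n <- nrow(adj)
  ord <- order(rowSums(adj), decreasing = TRUE)
  col <- integer(n)
  assign_next <- function(pos, max_used) {
    if (pos > n) return(TRUE)
    v <- ord[pos]
    neigh_cols <- col[adj[v, ] > 0]
    for (c in seq_len(min(k, max_used + 1L))) {
      if (!(c %in% neigh_cols)) {
        col[v] <<- c
        if (assign_next(pos + 1L, max(max_used, c))) return(TRUE)
        col[v] <<- 0L
      }
    }
    FALSE
  }
  assign_next(1L, 0L)
}

#' Connected-component statistics of a cell network
#'
#' Component number, Shannon entropy of the component vertex-mass
#' distribution (probabilities |c_i|/|G|, natural log), and the relative
#' vertex mass of the single largest component.
#'
#' @param net A `cell_network` with at least one node.
#' @return A one-row tibble: `n_components`, `component_mass_entropy`,
#'   `largest_component_fraction`.
#' @export
component_statistics <- function(net) {
  stopifnot(inherits(net, "cell_network"))
  if (igraph::vcount(net$graph) == 0L)
    stop("component_statistics: empty network")
  sizes <- igraph::components(net$graph)$csize
  p <- sizes / sum(sizes)
  tibble::tibble(
    n_components = length(sizes),
    component_mass_entropy = entropy_nats(p),
    largest_component_fraction = max(p)
  )
}

#' Box-counting fractal dimension of a binary set
#'
#' Slope of the least-squares fit of log N(eps) against log(1/eps), where
#' N(eps) counts the boxes of side eps (pixels, grid anchored at the image
#' origin) that intersect the foreground set. Applied to the rasterized
#' cell-body foreground of a label image, it measures the space-filling
#' behaviour of the cell network.
#'
#' @param x Binary/logical matrix, or a [label_image()] (foreground =
#'   labels > 0).
#' @param box_sizes Integer vector of box sides in pixels (>= 4 sizes). The
#'   default is powers of 2 from 2 up to a quarter of the smaller image
#'   side. For fixtures with a known self-similarity ratio, pass sizes
#'   matched to that ratio (e.g. powers of 3 for a Sierpinski carpet):
#'   the box-count sequence is then exact along the scaling relation.
#' @return The fitted dimension (numeric scalar) with attribute `counts`,
#'   a tibble of (box_size, n_boxes).
#' @export
fractal_dimension <- function(x, box_sizes = NULL) {
  if (inherits(x, "label_image")) x <- x$pixels > 0L
  if (!is.matrix(x)) stop("`x` must be a matrix or label_image")
  S <- x > 0
  if (!any(S)) stop("fractal_dimension: empty set")
  if (is.null(box_sizes)) {
    mx <- max(2L, floor(min(dim(S)) / 4))
    box_sizes <- 2^(1:floor(log2(mx)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 4L)
    stop("fractal_dimension: need at least 4 box sizes")
  idx <- which(S)
  r <- (idx - 1L) %% nrow(S)
  cc <- (idx - 1L) %/% nrow(S)
  n_boxes <- vapply(box_sizes, function(eps) {
    length(unique((r %/% eps) * (ncol(S) %/% eps + 2L) + (cc %/% eps)))
  }, 0)
  fit <- stats::lm(log(n_boxes) ~ log(1 / box_sizes))
  structure(unname(stats::coef(fit)[2]),
            counts = tibble::tibble(box_size = box_sizes, n_boxes = n_boxes))
}

#' All topology metrics of a cell network in one row
#'
#' Convenience wrapper combining [degree_statistics()],
#' [average_colorability()], [component_statistics()] and, when the source
#' label image is supplied, [fractal_dimension()] of its foreground.
#'
#' @param net A `cell_network`.
#' @param img Optional source [label_image()] for the fractal dimension.
#' @param exact_limit Passed to [average_colorability()].
#' @return A one-row tibble of the topology metrics.
#' @export
network_metrics <- function(net, img = NULL, exact_limit = 20L) {
  stopifnot(inherits(net, "cell_network"))
  if (igraph::vcount(net$graph) == 0L) {
    return(tibble::tibble(
      mean_degree = NA_real_, degree_variance = NA_real_,
      degree_entropy = NA_real_, avg_colorability = NA_real_,
      n_components = 0L, component_mass_entropy = NA_real_,
      largest_component_fraction = NA_real_, fractal_dimension = NA_real_
    ))
  }
  out <- dplyr::bind_cols(degree_statistics(net), component_statistics(net))
  out$avg_colorability <- as.numeric(average_colorability(net, exact_limit))
  out$fractal_dimension <- if (!is.null(img)) {
    as.numeric(tryCatch(fractal_dimension(img), error = function(e) NA_real_))
  } else NA_real_
  out[, c("mean_degree", "degree_variance", "degree_entropy",
          "avg_colorability", "n_components", "component_mass_entropy",
          "largest_component_fraction", "fractal_dimension")]
}
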