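#' Spearman correlation matrix across clones
#'
#' Rank correlation (mid-ranks for ties) of every pair of numeric
#' variables over clones, with pairwise-complete observations. A constant
#' variable has undefined correlations and yields NA against every other
#' variable.
#'
#' @param table Data frame with one row per clone: an id column (ignored)
#'   plus numeric measurement columns.
#' @param min_n Minimum number of clones required (default 3).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, min_n = 3L) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, TRUE)
  m <- as.matrix(table[, num, drop = FALSE])
  if (nrow(m) < min_n) stop("spearman_matrix: need >= ", min_n, " clones")
  r <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  # constant variables: cor() may return NA already; force NA off-diagonal
  const <- apply(m, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && length(unique(v)) == 1L
  })
  if (any(const)) {
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Threshold correlation graph of variables
#'
#' Variables become nodes (optionally labelled with their variable group:
#' 2D network topology, 2D single-cell morphology, 3D spheroid shape,
#' protrusions, disseminated cells); an edge joins every off-diagonal pair
#' with |r| strictly above `threshold`, carrying the coefficient, its sign
#' and magnitude.
#'
#' @param matrix Correlation matrix from [spearman_matrix()].
#' @param threshold Magnitude cutoff (default 0.8, as used for the
#'   all-variables graph; 0.3 for the invasion-only graph).
#' @param groups Optional named character vector mapping variable name to
#'   group label.
#' @return An object of class `correlation_graph`: `nodes` (tibble:
#'   variable, group), `edges` (tibble: from, to, r, sign, abs_r),
#'   `threshold`.
#' @export
correlation_graph <- function(matrix, threshold = 0.8, groups = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  vars <- colnames(matrix)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(matrix)))
  nodes <- tibble::tibble(
    variable = vars,
    group = if (is.null(groups)) NA_character_ else
      unname(groups[vars])
  )
  idx <- which(upper.tri(matrix) & !is.na(matrix) &
                 abs(matrix) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = vars[idx[, 1]],
    to = vars[idx[, 2]],
    r = matrix[idx],
    sign = ifelse(matrix[idx] >= 0, "positive", "negative"),
    abs_r = abs(matrix[idx])
  )
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph> %d variables, %d edges at |r| > %g\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Tidy the edges of a correlation graph
#' @param x A `correlation_graph`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.correlation_graph <- function(x, ...) x$edges

#' Convert a correlation graph to igraph
#' @param net A `correlation_graph`.
#' @return An igraph graph with `group` vertex attribute and `r`, `sign`,
#'   `abs_r` edge attributes; suitable for GraphML export.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "correlation_graph"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$variable,
                          group = ifelse(is.na(net$nodes$group), "",
                                         net$nodes$group)))
}

#' Correlations of 2D variables with the composite invasion score
#'
#' Builds the star graph around `invasion3D`: the Spearman correlation of
#' every other (2D) variable with the composite invasion score, keeping
#' only edges with |r| strictly above `threshold` (default 0.3).
#' Correlations among the 2D variables themselves are excluded.
#'
#' @param table Data frame over clones containing an `invasion3D` column
#'   and 2D variable columns.
#' @param threshold Magnitude cutoff (default 0.3).
#' @param groups Optional variable-to-group mapping.
#' @return A `correlation_graph` whose edges are all incident to
#'   `invasion3D`.
#' @export
invasion_correlations <- function(table, threshold = 0.3, groups = NULL) {
  stopifnot(is.data.frame(table))
  if (!"invasion3D" %in% names(table))
    stop("invasion_correlations: no invasion3D column")
  r <- spearman_matrix(table)
  keep <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  keep["invasion3D", ] <- TRUE
  keep[, "invasion3D"] <- TRUE
  r[!keep] <- NA_real_
  diag(r) <- 1
  g <- correlation_graph(r, threshold = threshold, groups = groups)
  g$edges <- g$edges[g$edges$from == "invasion3D" |
                       g$edges$to == "invasion3D", , drop = FALSE]
  g
}

#' The paper-style variable grouping
#'
#' Convenience constructor of the five variable groups used for graph
#' colouring: 2D network topology, 2D single-cell morphology, 3D spheroid
#' shape, 3D protrusions, 3D disseminated cells.
#'
#' @param network2D,singlecell2D,spheroid_shape3D,protrusion3D,dissemination3D
#'   Character vectors of member variable names (disjoint).
#' @return Named character vector mapping variable name to group.
#' @export
variable_groups <- function(network2D = character(),
                            singlecell2D = character(),
                            spheroid_shape3D = character(),
                            protrusion3D = character(),
                            dissemination3D = character()) {
  all_vars <- c(network2D, singlecell2D, spheroid_shape3D, protrusion3D,
                dissemination3D)
  if (anyDuplicated(all_vars))
    stop("variable groups must be disjoint")
  stats::setNames(
    rep(c("network2D", "singlecell2D", "spheroid_shape3D", "protrusion3D",
          "dissemination3D"),
        c(length(network2D), length(singlecell2D), length(spheroid_shape3D),
          length(protrusion3D), length(dissemination3D))),
    all_vars)
}

#' Plot a correlation graph
#'
#' Circular layout; solid edges are positive correlations, dashed
#' negative, line width proportional to |r|, nodes coloured by variable
#' group.
#'
#' @param object A `correlation_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_graph <- function(object, ...) {
  n <- nrow(object$nodes)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  pos <- tibble::tibble(variable = object$nodes$variable,
                        group = object$nodes$group,
                        x = cos(ang), y = sin(ang))
  ed <- dplyr::left_join(object$edges, pos[, c("variable", "x", "y")],
                         by = c("from" = "variable"))
  ed <- dplyr::left_join(ed, pos[, c("variable", "x", "y")],
                         by = c("to" = "variable"),
                         suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign,
                   linewidth = .data$abs_r), colour = "grey40") +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$group), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$variable), size = 3) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(linetype = "sign", linewidth = "|r|", colour = "group")
}
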