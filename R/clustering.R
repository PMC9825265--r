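#' Hierarchically cluster clones by growth variables
#'
#' Variables are z-scored across clones (constant variables dropped with a
#' warning), clones are clustered by Ward-linkage agglomeration on
#' Euclidean distance, and flat labels come from a horizontal cut giving
#' exactly `k` clusters.
#'
#' @param vectors Data frame with a `clone_id` column and numeric growth
#'   variables (one row per clone); see [growth_variable_table()].
#' @param k Number of flat clusters to cut (2 <= k <= n clones).
#' @param impute_limit Maximum fraction of missing entries per variable
#'   imputed by the per-variable median; clones still incomplete after
#'   imputation are dropped with a warning.
#' @return An object of class `clone_clusters`: `hclust` (the linkage
#'   tree), `labels` (tibble clone_id, cluster), `k`, `scaling`
#'   (per-variable mean and sd), `variables`.
#' @export
cluster_clones <- function(vectors, k, impute_limit = 0.1) {
  z <- standardize_vectors(vectors, impute_limit)
  n <- nrow(z$mat)
  if (n < 2L) stop("cluster_clones: need >= 2 clones")
  if (k > n) stop("cluster_clones: k exceeds the number of clones")
  hc <- stats::hclust(stats::dist(z$mat), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(
    list(hclust = hc,
         labels = tibble::tibble(clone_id = rownames(z$mat),
                                 cluster = unname(cl)),
         k = as.integer(k), scaling = z$scaling, variables = z$variables),
    class = "clone_clusters"
  )
}

# z-score variables across clones; returns matrix with clone_id rownames
standardize_vectors <- function(vectors, impute_limit = 0.1) {
  stopifnot(is.data.frame(vectors), "clone_id" %in% names(vectors))
  num <- vapply(vectors, is.numeric, TRUE)
  vars <- names(vectors)[num]
  if (!length(vars)) stop("no numeric growth variables")
  m <- as.matrix(vectors[, vars, drop = FALSE])
  rownames(m) <- as.character(vectors$clone_id)
  # median imputation, but only for sparsely missing variables
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss) && mean(miss) <= impute_limit) {
      m[miss, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  bad_rows <- apply(m, 1L, anyNA)
  if (any(bad_rows)) {
    warning("dropping ", sum(bad_rows),
            " clone(s) with missing growth variables")
    m <- m[!bad_rows, , drop = FALSE]
  }
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  const <- sd == 0 | is.na(sd)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    mu <- mu[!const]; sd <- sd[!const]
  }
  if (!ncol(m)) stop("no non-constant growth variables remain")
  list(mat = sweep(sweep(m, 2L, mu), 2L, sd, "/"),
       scaling = tibble::tibble(variable = colnames(m), mean = mu, sd = sd),
       variables = colnames(m))
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("<clone_clusters> %d clones, %d variables, k = %d\n",
              nrow(x$labels), length(x$variables), x$k))
  print(table(x$labels$cluster))
  invisible(x)
}

#' Tidy flat cluster labels
#' @param x A `clone_clusters`.
#' @param ... Unused.
#' @return Tibble: clone_id, cluster.
#' @export
tidy.clone_clusters <- function(x, ...) x$labels

#' One-row summary of a clustering
#' @param x A `clone_clusters`.
#' @param ... Unused.
#' @return Tibble: n_clones, n_variables, k, cut_height.
#' @export
glance.clone_clusters <- function(x, ...) {
  h <- sort(x$hclust$height, decreasing = TRUE)
  cut_height <- if (x$k > 1L && x$k <= length(h)) {
    mean(h[c(x$k - 1L, x$k)][!is.na(h[c(x$k - 1L, x$k)])])
  } else NA_real_
  tibble::tibble(n_clones = nrow(x$labels),
                 n_variables = length(x$variables),
                 k = x$k, cut_height = cut_height)
}

#' Two-stage clustering into superclasses and subclasses
#'
#' Stage 1 cuts all clones into `k_super` superclasses (the parental-line
#' split); stage 2 reclusters within each superclass into `k_sub`
#' subclasses. When known line identities are supplied, the best
#' label-matched agreement of the stage-1 cut with them is reported.
#'
#' @param vectors As in [cluster_clones()].
#' @param superclass_labels Optional vector (aligned with `vectors` rows)
#'   of known line ids.
#' @param k_super,k_sub Cluster counts for the two stages (defaults 2
#'   and 3).
#' @return An object of class `two_stage_clusters`: `superclasses` (a
#'   `clone_clusters`), `subclasses` (list of `clone_clusters`, one per
#'   superclass), `labels` (tibble clone_id, superclass, subclass,
#'   subclass_global), and `superclass_agreement` (fraction, or NA).
#' @export
two_stage_clustering <- function(vectors, superclass_labels = NULL,
                                 k_super = 2L, k_sub = 3L) {
  stage1 <- cluster_clones(vectors, k = k_super)
  agreement <- NA_real_
  if (!is.null(superclass_labels)) {
    known <- superclass_labels[match(stage1$labels$clone_id,
                                     as.character(vectors$clone_id))]
    agreement <- best_label_agreement(stage1$labels$cluster, known)
  }
  subclasses <- list()
  labels <- stage1$labels
  labels$subclass <- NA_integer_
  for (s in sort(unique(stage1$labels$cluster))) {
    ids <- stage1$labels$clone_id[stage1$labels$cluster == s]
    sub_vec <- vectors[as.character(vectors$clone_id) %in% ids, , drop = FALSE]
    if (nrow(sub_vec) < k_sub)
      stop("superclass ", s, " has fewer than k_sub = ", k_sub, " clones")
    sub <- cluster_clones(sub_vec, k = k_sub)
    subclasses[[as.character(s)]] <- sub
    labels$subclass[match(sub$labels$clone_id, labels$clone_id)] <-
      sub$labels$cluster
  }
  names(labels)[names(labels) == "cluster"] <- "superclass"
  labels$subclass_global <- paste0(labels$superclass, ".", labels$subclass)
  structure(
    list(superclasses = stage1, subclasses = subclasses, labels = labels,
         superclass_agreement = agreement),
    class = "two_stage_clusters"
  )
}

# best agreement between a k-cluster labelling and known classes over all
# assignments of clusters to classes (k is small: 2 in practice)
best_label_agreement <- function(cluster, known) {
  ok <- !is.na(known)
  cluster <- cluster[ok]; known <- as.factor(known[ok])
  cl_lev <- unique(cluster)
  perms <- perm_list(seq_along(cl_lev))
  best <- 0
  for (p in perms) {
    mapped <- levels(known)[pmin(p[match(cluster, cl_lev)], nlevels(known))]
    best <- max(best, mean(mapped == as.character(known)))
  }
  best
}

perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' @export
print.two_stage_clusters <- function(x, ...) {
  cat(sprintf("<two_stage_clusters> %d clones: %d superclasses x %d subclasses\n",
              nrow(x$labels), x$superclasses$k,
              x$subclasses[[1]]$k))
  if (!is.na(x$superclass_agreement))
    cat(sprintf("  superclass agreement with known lines: %.1f%%\n",
                100 * x$superclass_agreement))
  print(table(x$labels$subclass_global))
  invisible(x)
}

#' @export
tidy.two_stage_clusters <- function(x, ...) x$labels

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items; 1 means
#' identical partitions, 0 is the expectation under random labellings.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Deterministic 2D embedding of clone growth-variable vectors
#'
#' A principal-component projection of the z-scored growth variables onto
#' two dimensions, with a fixed sign convention so coordinates are
#' reproducible. The embedding is a visual aid for inspecting the
#' clustering, not an inferential tool.
#'
#' @param vectors As in [cluster_clones()] (>= 4 clones).
#' @return Tibble: clone_id, dim1, dim2.
#' @export
embed_clones <- function(vectors) {
  z <- standardize_vectors(vectors)
  if (nrow(z$mat) < 4L) stop("embed_clones: need >= 4 clones")
  pc <- stats::prcomp(z$mat, center = FALSE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  # sign convention: largest-magnitude loading of each axis is positive
  for (j in 1:2) {
    if (ncol(pc$rotation) >= j) {
      l <- pc$rotation[, j]
      if (l[which.max(abs(l))] < 0) coords[, j] <- -coords[, j]
    }
  }
  tibble::tibble(clone_id = rownames(z$mat),
                 dim1 = coords[, 1], dim2 = coords[, 2])
}

#' Dendrogram plot of a clone clustering
#'
#' @param object A `clone_clusters`.
#' @param ... Unused.
#' @return A ggplot object: the Ward linkage tree with leaves coloured by
#'   flat cluster.
#' @export
autoplot.clone_clusters <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  leaves <- tibble::tibble(
    x = seq_along(object$hclust$order),
    clone_id = object$hclust$labels[object$hclust$order]
  )
  leaves$cluster <- factor(
    object$labels$cluster[match(leaves$clone_id, object$labels$clone_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)) +
    ggplot2::geom_point(
      data = leaves,
      ggplot2::aes(x = .data$x, y = 0, colour = .data$cluster), size = 2) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$clone_id) +
    ggplot2::labs(x = NULL, y = "merge height (Ward)", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# segment coordinates of an hclust tree in leaf-order x units
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- list()
  pos <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  hgt <- function(id) if (id < 0) 0 else node_h[id]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- pos(a); xb <- pos(b)
    node_x[i] <- (xa + xb) / 2
    seg[[length(seg) + 1L]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(hgt(a), hgt(b), node_h[i]), yend = c(node_h[i], node_h[i],
                                                 node_h[i])
    )
  }
  dplyr::bind_rows(seg)
}
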