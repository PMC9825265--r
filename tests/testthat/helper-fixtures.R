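# Shared fixtures, all generated in code.

# disc label image: radius um, centred, single label
disc_image <- function(radius_um, pixel_size = 1, pad = 6) {
  r <- radius_um / pixel_size
  s <- ceiling(2 * r + 2 * pad)
  m <- matrix(0L, s, s)
  cen <- (s + 1) / 2
  m[(row(m) - cen)^2 + (col(m) - cen)^2 <= r^2] <- 1L
  label_image(m, pixel_size)
}

# two discs of given radius with centre separation (um); integer centres so
# the rasterized boundary gap equals the analytic gap exactly
two_disc_image <- function(radius_um, separation_um, pixel_size = 1) {
  r <- radius_um / pixel_size
  sep <- separation_um / pixel_size
  h <- ceiling(2 * r + 14)
  w <- ceiling(2 * r + sep + 14)
  m <- matrix(0L, h, w)
  c1 <- c(r + 7, r + 7)
  c2 <- c(r + 7, r + 7 + sep)
  d1 <- (row(m) - c1[1])^2 + (col(m) - c1[2])^2 <= r^2
  d2 <- (row(m) - c2[1])^2 + (col(m) - c2[2])^2 <= r^2
  m[d1] <- 1L
  m[d2] <- 2L
  label_image(m, pixel_size)
}

# axis-aligned rectangles as labels: list of c(r0, r1, c0, c1)
rect_image <- function(rects, nrow, ncol, pixel_size = 1) {
  m <- matrix(0L, nrow, ncol)
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  label_image(m, pixel_size)
}

# Sierpinski carpet raster of given depth (3^depth pixels per side)
sierpinski_carpet <- function(depth) {
  if (depth == 0L) return(matrix(1L, 1L, 1L))
  s <- sierpinski_carpet(depth - 1L)
  n <- nrow(s)
  out <- matrix(0L, 3L * n, 3L * n)
  for (i in 0:2) for (j in 0:2) {
    if (!(i == 1 && j == 1)) out[i * n + 1:n, j * n + 1:n] <- s
  }
  out
}

# random adjacency matrix on n nodes with edge probability p
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  if (n >= 2) {
    up <- which(upper.tri(a))
    a[up] <- as.integer(stats::runif(length(up)) < p)
    a <- a + t(a)
  }
  a
}

adjacency_to_network <- function(adj) {
  e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  cell_network_from_edges(nrow(adj), e)
}

# nested 2-superclass x 3-subclass growth-variable panel with planted
# labels; separation is the between-group offset in units of within sd
nested_clone_panel <- function(n_per = 10, separation = 4, sd = 1,
                               n_vars = 6, seed = 42) {
  set.seed(seed)
  # offsets live along two orthogonal directions spanning every variable,
  # so z-scoring cannot flatten the planted structure: superclass centres
  # are 10*separation*sd apart, subclass centres 2*separation*sd apart
  e1 <- rep(1, n_vars) / sqrt(n_vars)
  e2 <- rep_len(c(1, -1), n_vars) / sqrt(n_vars)
  rows <- list()
  super <- integer(0)
  sub <- character(0)
  for (s in 1:2) for (b in 1:3) {
    centre <- (s * 10 * separation * sd) * e1 +
      (b * 2 * separation * sd) * e2
    for (i in seq_len(n_per)) {
      rows[[length(rows) + 1L]] <- centre + stats::rnorm(n_vars, 0, sd)
      super <- c(super, s)
      sub <- c(sub, paste(s, b))
    }
  }
  m <- do.call(rbind, rows)
  vectors <- tibble::as_tibble(as.data.frame(m))
  names(vectors) <- paste0("v", seq_len(n_vars))
  vectors <- dplyr::bind_cols(
    tibble::tibble(clone_id = sprintf("cl%02d", seq_len(nrow(m)))), vectors)
  list(vectors = vectors, super = super, sub = sub)
}

# --- independent brute-force oracles -------------------------------------

# degree statistics straight from the adjacency matrix
oracle_degree_stats <- function(adj) {
  deg <- rowSums(adj)
  n <- length(deg)
  p <- as.numeric(table(deg)) / n
  list(mean = mean(deg), var = mean((deg - mean(deg))^2),
       entropy = -sum(p * log(p)))
}

# connected components by hand-rolled BFS
oracle_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    q <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      size <- size + 1L
      nb <- which(adj[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      q <- c(q, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# chromatic number by plain backtracking in natural vertex order (no
# ordering heuristics, no clique bound): independent of the package path
oracle_chromatic <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  try_k <- function(k) {
    col <- integer(n)
    rec <- function(v) {
      if (v > n) return(TRUE)
      for (c in seq_len(k)) {
        if (!any(col[adj[v, ] > 0] == c)) {
          col[v] <<- c
          if (rec(v + 1L)) return(TRUE)
          col[v] <<- 0L
        }
      }
      FALSE
    }
    rec(1L)
  }
  k <- 1L
  while (!try_k(k)) k <- k + 1L
  k
}

# Spearman by explicit mid-rank transform then Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}
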