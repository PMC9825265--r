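#' Shannon entropy of a set of measurements
#'
#' H(x) = -sum_i P(x_i) ln P(x_i), natural log, with 0 * ln 0 := 0.
#' P is the empirical distribution of the values over bins.
#'
#' @param values Numeric vector (>= 1 value).
#' @param bins Binning rule: `"fd"` (Freedman-Diaconis histogram bins, the
#'   default for continuous shape properties), `"exact"` (one bin per
#'   distinct value; use for discrete quantities such as vertex degrees),
#'   a single integer bin count, or a numeric vector of break points.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(values, bins = "fd") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("shannon_entropy: no values")
  if (identical(bins, "exact")) {
    p <- as.numeric(table(values)) / length(values)
    return(entropy_nats(p))
  }
  if (length(unique(values)) == 1L) return(0)
  if (identical(bins, "fd")) {
    k <- grDevices::nclass.FD(values)
    breaks <- seq(min(values), max(values), length.out = k + 1L)
  } else if (length(bins) == 1L && is.numeric(bins)) {
    breaks <- seq(min(values), max(values), length.out = bins + 1L)
  } else {
    breaks <- bins
  }
  cnt <- graphics::hist(values, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  entropy_nats(cnt / sum(cnt))
}

# entropy (nats) of a probability vector; zero-probability bins contribute 0
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# population variance (denominator n): a snapshot is the full observed
# population of the image, not a sample from it
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Measure per-cell shape properties
#'
#' One record per label: centroid (um), area (um^2), circumference (um,
#' contour arc length with chain-code correction), circularity
#' 4*pi*A/P^2 (clipped to 1), and aspect ratio (major/minor axis of the
#' inertia-equivalent ellipse, >= 1). Cells touching the image border are
#' flagged: their truncated shapes bias morphology, so population summaries
#' exclude them, but they remain nodes of the adjacency network.
#'
#' @param img A [label_image()].
#' @return A tibble with one row per cell: `cell_id`, `x_um`, `y_um`,
#'   `area_um2`, `circumference_um`, `circularity`, `aspect_ratio`,
#'   `on_border`.
#' @export
measure_cells <- function(img) {
  stopifnot(inherits(img, "label_image"))
  px <- img$pixels
  ps <- img$pixel_size
  k <- max(px)
  if (k == 0L) {
    return(tibble::tibble(
      cell_id = integer(), x_um = double(), y_um = double(),
      area_um2 = double(), circumference_um = double(),
      circularity = double(), aspect_ratio = double(), on_border = logical()
    ))
  }
  idx <- which(px > 0L)
  lab <- px[idx]
  rows <- (idx - 1L) %% nrow(px) + 1L
  cols <- (idx - 1L) %/% nrow(px) + 1L
  areas_px <- tabulate(lab, nbins = k)
  cx <- vapply(split((cols - 1), lab), mean, 0)  # 0-based physical
  cy <- vapply(split((rows - 1), lab), mean, 0)
  border <- sort(unique(c(
    px[1L, ], px[nrow(px), ], px[, 1L], px[, ncol(px)]
  )))
  on_border <- seq_len(k) %in% border[border > 0L]
  perim <- perimeter_per_label(px, k) * ps
  ar <- vapply(seq_len(k), function(l) {
    sel <- lab == l
    aspect_ratio_moments(rows[sel], cols[sel])
  }, 0)
  area <- areas_px * ps^2
  circ <- pmin(1, 4 * pi * area / perim^2)
  tibble::tibble(
    cell_id = seq_len(k),
    x_um = cx * ps, y_um = cy * ps,
    area_um2 = area,
    circumference_um = perim,
    circularity = circ,
    aspect_ratio = ar,
    on_border = on_border
  )
}

# Aspect ratio from second central moments of pixel coordinates, with the
# 1/12 per-pixel variance term so single-pixel objects are non-degenerate.
aspect_ratio_moments <- function(rows, cols) {
  mu <- c(mean(rows), mean(cols))
  dr <- rows - mu[1]; dc <- cols - mu[2]
  m20 <- mean(dr^2) + 1 / 12
  m02 <- mean(dc^2) + 1 / 12
  m11 <- mean(dr * dc)
  ev <- eigen(matrix(c(m20, m11, m11, m02), 2L), symmetric = TRUE)$values
  sqrt(max(ev[1], 0) / max(ev[2], .Machine$double.eps))
}

# Perimeter (pixels) per label: arc length of the smoothed outer contour
# polygon plus pi. Raw boundary-pixel chains overestimate smooth boundaries
# resolution-dependently (stair-casing), which would depress circularity;
# a circular moving average removes the zigzag, and the +pi term accounts
# for the half-pixel band between pixel centers and the true object
# boundary (Minkowski dilation of a simple closed curve by radius 1/2).
perimeter_per_label <- function(px, k) {
  contours <- EBImage::ocontour(px)
  out <- rep(NA_real_, k)
  for (nm in seq_along(contours)) {
    cc <- contours[[nm]]
    l <- suppressWarnings(as.integer(names(contours)[nm]))
    if (is.na(l)) l <- nm
    out[l] <- contour_perimeter(cc)
  }
  out
}

contour_perimeter <- function(cc, window = 5L) {
  n <- nrow(cc)
  if (n <= 1L) return(4)          # isolated pixel: unit square boundary
  if (n == 2L) return(6)          # domino
  w <- min(window, n)
  if (w %% 2L == 0L) w <- w - 1L
  if (w >= 3L) {
    h <- (w - 1L) %/% 2L
    for (j in 1:2) {
      v <- cc[, j]
      s <- stats::filter(c(utils::tail(v, h), v, utils::head(v, h)),
                         rep(1 / w, w), sides = 2)
      cc[, j] <- s[(h + 1L):(h + n)]
    }
  }
  d <- rbind(cc[-1L, , drop = FALSE], cc[1L, , drop = FALSE]) - cc
  sum(sqrt(rowSums(d^2))) + pi
}

#' Summarize a label image as a population snapshot
#'
#' Computes confluency (foreground pixel fraction) and the mean, population
#' variance and Shannon entropy of each shape property over non-border
#' cells. A snapshot is one point of a clone's density-dependent
#' morphological progression.
#'
#' @param img A [label_image()].
#' @param entropy_bins Binning rule passed to [shannon_entropy()].
#' @return An object of class `population_snapshot` with fields `image_id`,
#'   `clone_id`, `time_h`, `confluency`, `cells` (per-cell tibble) and
#'   `summary` (long tibble: property, mean, variance, entropy).
#' @export
snapshot <- function(img, entropy_bins = "fd") {
  stopifnot(inherits(img, "label_image"))
  cells <- measure_cells(img)
  confluency <- mean(img$pixels > 0L)
  props <- c("area_um2", "circumference_um", "circularity", "aspect_ratio")
  usable <- cells[!cells$on_border, , drop = FALSE]
  summ <- purrr::map_dfr(props, function(p) {
    v <- usable[[p]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      tibble::tibble(property = p, mean = NA_real_, variance = NA_real_,
                     entropy = NA_real_)
    } else {
      tibble::tibble(property = p, mean = mean(v), variance = pop_var(v),
                     entropy = shannon_entropy(v, bins = entropy_bins))
    }
  })
  structure(
    list(image_id = img$image_id, clone_id = img$clone_id,
         time_h = img$time_h, confluency = confluency,
         n_cells = nrow(cells), cells = cells, summary = summ),
    class = "population_snapshot"
  )
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf("<population_snapshot> %s (clone %s): %d cells, confluency %.3f\n",
              x$image_id, x$clone_id, x$n_cells, x$confluency))
  print(x$summary)
  invisible(x)
}

#' Tidy a population snapshot into one wide row
#'
#' One row per snapshot with `confluency`, `n_cells` and
#' `<property>_<stat>` columns; the row format consumed by
#' [clone_progression()].
#'
#' @param x A `population_snapshot`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.population_snapshot <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(x$summary, c("mean", "variance", "entropy"),
                        names_to = "stat"),
    names_from = c("property", "stat"), values_from = "value",
    names_glue = "{property}_{stat}"
  )
  dplyr::bind_cols(
    tibble::tibble(image_id = x$image_id, clone_id = x$clone_id,
                   time_h = x$time_h, confluency = x$confluency,
                   n_cells = x$n_cells),
    wide
  )
}
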