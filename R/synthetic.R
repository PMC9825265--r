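#' Specification for a synthetic cell population
#'
#' Cells are perturbed ellipses placed by rejection sampling, so area,
#' centroid and pairwise boundary gaps have analytic (polygon) ground
#' truth. Placement avoids planted gaps inside an ambiguity band around the
#' 5 um adjacency threshold (half-width `2 * pixel_size`), so rasterized
#' boundary distances and analytic polygon distances always agree on which
#' side of the threshold a pair falls.
#'
#' @param n_cells Number of cells to place.
#' @param target_confluency Fraction of the image to cover, in [0, 1]; sets
#'   the image side given the expected total cell area.
#' @param axis_um Range (min, max) of ellipse semi-axes in micrometres.
#' @param perturb Relative amplitude of smooth radial boundary
#'   perturbation (0 = exact ellipses).
#' @param min_gap Minimum allowed edge-to-edge gap between planted cells
#'   (um, > 0).
#' @param adjacency_um Gap threshold defining ground-truth adjacency
#'   (default 5 um, matching [build_network()]).
#' @param pixel_size Micrometres per pixel of the rasterized image.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `synthetic_population_spec`.
#' @export
synthetic_population_spec <- function(n_cells, target_confluency = 0.3,
                                      axis_um = c(8, 16), perturb = 0.08,
                                      min_gap = 1, adjacency_um = 5,
                                      pixel_size = 1, seed = 1L) {
  stopifnot(n_cells >= 0, target_confluency >= 0, target_confluency <= 1,
            all(axis_um > 0), length(axis_um) == 2L, perturb >= 0,
            min_gap > 0, pixel_size > 0)
  structure(
    list(n_cells = as.integer(n_cells),
         target_confluency = target_confluency,
         axis_um = sort(axis_um), perturb = perturb, min_gap = min_gap,
         adjacency_um = adjacency_um, pixel_size = pixel_size,
         seed = as.integer(seed)),
    class = "synthetic_population_spec"
  )
}

#' Generate a synthetic cell population with ground truth
#'
#' @param spec A [synthetic_population_spec()].
#' @param image_id,clone_id Identifiers stamped on the label image.
#' @return A list with elements `image` (a [label_image()]), `cells`
#'   (tibble: cell_id, analytic x_um/y_um/area_um2), and `adjacency`
#'   (tibble of cell id pairs with planted boundary gap below
#'   `adjacency_um`, plus the gap itself).
#' @export
generate_population <- function(spec, image_id = "synthetic",
                                clone_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_population_spec"))
  ps <- spec$pixel_size
  n <- spec$n_cells
  mean_area <- pi * mean(spec$axis_um)^2
  if (n == 0L) {
    img <- label_image(matrix(0L, 128L, 128L), ps, image_id = image_id,
                       clone_id = clone_id)
    return(list(
      image = img,
      cells = tibble::tibble(cell_id = integer(), x_um = double(),
                             y_um = double(), area_um2 = double()),
      adjacency = tibble::tibble(from = integer(), to = integer(),
                                 gap_um = double())
    ))
  }
  conf <- max(spec$target_confluency, 0.02)
  margin <- spec$axis_um[2] * 1.6 + 4 * ps
  side_um <- sqrt(n * mean_area / conf) + 2 * margin
  side_px <- ceiling(side_um / ps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  band <- 2 * ps  # ambiguity half-width around the adjacency threshold
  polys <- vector("list", n)
  dense <- vector("list", n)  # densely resampled boundaries for distances
  attempts_left <- 150L * n
  placed <- 0L
  while (placed < n) {
    if (attempts_left <= 0L)
      stop("infeasible packing: could not place ", n, " cells at confluency ",
           spec$target_confluency)
    attempts_left <- attempts_left - 1L
    cen <- stats::runif(2, margin, side_um - margin)
    poly <- perturbed_ellipse(cen,
                              a = stats::runif(1, spec$axis_um[1], spec$axis_um[2]),
                              b = stats::runif(1, spec$axis_um[1], spec$axis_um[2]),
                              theta = stats::runif(1, 0, pi),
                              perturb = spec$perturb)
    dpts <- densify_polygon(poly, max_step = ps / 4)
    ok <- TRUE
    cutoff <- max(spec$min_gap, spec$adjacency_um + band) + ps
    if (placed > 0L) {
      for (j in seq_len(placed)) {
        g <- polygon_gap(dpts, dense[[j]], cutoff = cutoff)
        if (g < spec$min_gap ||
            (g > spec$adjacency_um - band && g < spec$adjacency_um + band)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      placed <- placed + 1L
      polys[[placed]] <- poly
      dense[[placed]] <- dpts
    }
  }

  px <- matrix(0L, side_px, side_px)
  for (i in seq_len(n)) {
    px <- rasterize_polygon(px, polys[[i]], ps, label = i)
  }
  cells <- purrr::map_dfr(seq_len(n), function(i) {
    g <- polygon_geometry(polys[[i]])
    tibble::tibble(cell_id = i, x_um = g$cx, y_um = g$cy, area_um2 = g$area)
  })
  adjacency <- tibble::tibble(from = integer(), to = integer(),
                              gap_um = double())
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        g <- polygon_gap(dense[[i]], dense[[j]],
                         cutoff = spec$adjacency_um + ps)
        if (g < spec$adjacency_um) {
          adjacency <- dplyr::bind_rows(
            adjacency, tibble::tibble(from = i, to = j, gap_um = g))
        }
      }
    }
  }
  img <- label_image(px, ps, image_id = image_id, clone_id = clone_id)
  list(image = img, cells = cells, adjacency = adjacency)
}

# --- polygon helpers (x = column direction um, y = row direction um) ------

# closed polygon (m x 2: x, y) of an ellipse with smooth radial perturbation
perturbed_ellipse <- function(center, a, b, theta, perturb, m = 90L) {
  phi <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  r_mod <- rep(1, m)
  if (perturb > 0) {
    noise <- stats::rnorm(m)
    w <- 9L
    h <- (w - 1L) %/% 2L
    sm <- stats::filter(c(utils::tail(noise, h), noise, utils::head(noise, h)),
                        rep(1 / w, w), sides = 2)
    sm <- as.numeric(sm[(h + 1L):(h + m)])
    r_mod <- pmax(0.5, 1 + perturb * sm / stats::sd(sm))
  }
  ex <- a * cos(phi) * r_mod
  ey <- b * sin(phi) * r_mod
  x <- center[1] + ex * cos(theta) - ey * sin(theta)
  y <- center[2] + ex * sin(theta) + ey * cos(theta)
  cbind(x = x, y = y)
}

# resample polygon boundary so consecutive points are <= max_step apart
densify_polygon <- function(poly, max_step) {
  m <- nrow(poly)
  nxt <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  out <- vector("list", m)
  for (i in seq_len(m)) {
    len <- sqrt(sum((nxt[i, ] - poly[i, ])^2))
    k <- max(1L, ceiling(len / max_step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(poly[i, 1] + t * (nxt[i, 1] - poly[i, 1]),
                      poly[i, 2] + t * (nxt[i, 2] - poly[i, 2]))
  }
  do.call(rbind, out)
}

# minimum distance between two densely sampled boundaries (um); returns Inf
# when bounding boxes are separated by more than `cutoff` (only gaps below
# the adjacency threshold + ambiguity band are ever needed exactly)
polygon_gap <- function(a, b, cutoff = 10) {
  if (min(a[, 1]) > max(b[, 1]) + cutoff || min(b[, 1]) > max(a[, 1]) + cutoff ||
      min(a[, 2]) > max(b[, 2]) + cutoff || min(b[, 2]) > max(a[, 2]) + cutoff)
    return(Inf)
  best <- Inf
  nb <- nrow(b)
  chunk <- 2048L
  for (s in seq(1L, nb, by = chunk)) {
    e <- min(nb, s + chunk - 1L)
    d2 <- outer(a[, 1], b[s:e, 1], "-")^2 + outer(a[, 2], b[s:e, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# shoelace area and centroid of a closed polygon
polygon_geometry <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  area <- sum(cr) / 2
  cx <- sum((x + xs) * cr) / (6 * area)
  cy <- sum((y + ys) * cr) / (6 * area)
  list(area = abs(area), cx = cx, cy = cy)
}

# scanline even-odd fill of a polygon onto a label matrix; pixel centre of
# (row i, col j), 1-based, sits at (x, y) = ((j-1) ps, (i-1) ps)
rasterize_polygon <- function(px, poly, ps, label) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  r0 <- max(1L, floor(min(y) / ps) + 1L)
  r1 <- min(nrow(px), ceiling(max(y) / ps) + 1L)
  for (i in r0:r1) {
    yc <- (i - 1) * ps
    crosses <- which((y <= yc & ys > yc) | (ys <= yc & y > yc))
    if (length(crosses) < 2L) next
    xc <- x[crosses] + (yc - y[crosses]) / (ys[crosses] - y[crosses]) *
      (xs[crosses] - x[crosses])
    xc <- sort(xc)
    for (s in seq(1L, length(xc) - 1L, by = 2L)) {
      c0 <- max(1L, ceiling(xc[s] / ps) + 1L)
      c1 <- min(ncol(px), floor(xc[s + 1L] / ps) + 1L)
      if (c0 <= c1) px[i, c0:c1] <- label
    }
  }
  px
}

# save/restore global RNG state so generators do not disturb user RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a clone's density-dependent progression with planted trends
#'
#' For each property, the value at confluency d is drawn as
#' `quadratic(d) + Gaussian(0, sd)`; the planted polynomial coefficients
#' are returned as ground truth for regression-recovery tests.
#'
#' @param coefficients Named list; each element a numeric coefficient
#'   vector (ascending powers) for one property.
#' @param densities Confluency fractions in [0, 1] at which snapshots are
#'   simulated.
#' @param noise_sd Gaussian noise standard deviation (scalar or per
#'   property).
#' @param clone_id Identifier.
#' @param seed Integer seed.
#' @return A list with `points` (tibble: clone_id, confluency, one column
#'   per property) and `truth` (the planted coefficients).
#' @export
generate_progression <- function(coefficients, densities,
                                 noise_sd = 0, clone_id = "clone",
                                 seed = 1L) {
  stopifnot(is.list(coefficients), length(names(coefficients)) > 0,
            all(densities >= 0), all(densities <= 1))
  noise_sd <- rep(noise_sd, length.out = length(coefficients))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vals <- purrr::imap(coefficients, function(cf, nm) {
    i <- match(nm, names(coefficients))
    mu <- polynomial_eval(cf, densities)
    mu + stats::rnorm(length(densities), 0, noise_sd[i])
  })
  points <- dplyr::bind_cols(
    tibble::tibble(clone_id = clone_id, confluency = densities),
    tibble::as_tibble(vals)
  )
  list(points = points, truth = coefficients)
}

polynomial_eval <- function(coef, x) {
  out <- numeric(length(x))
  for (p in seq_along(coef)) out <- out + coef[p] * x^(p - 1L)
  out
}

#' Specification for a synthetic spheroid z-stack
#'
#' The spheroid body is a ball; protrusions are capsules (thick radial
#' segments) from the body centroid with exact tip-to-centroid lengths;
#' disseminated cells are off-body discs at exact centroid-to-centroid
#' distances. Planted structures must not overlap.
#'
#' @param body_radius Body radius, um.
#' @param protrusion_lengths Tip-to-centroid distances, um (all >
#'   `body_radius`).
#' @param protrusion_width Capsule width, um.
#' @param disseminated_distances Centroid-to-centroid distances, um (all >
#'   `body_radius`).
#' @param disseminated_areas Blob areas, um^2 (recycled).
#' @param n_slices Number of z slices (>= 15).
#' @param z_spacing Slice spacing, um (default 5).
#' @param pixel_size In-plane um/px.
#' @param noise_sd Additive Gaussian intensity noise (intensities are on
#'   [0, 1]).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spheroid_spec`.
#' @export
synthetic_spheroid_spec <- function(body_radius = 200,
                                    protrusion_lengths = numeric(),
                                    protrusion_width = 30,
                                    disseminated_distances = numeric(),
                                    disseminated_areas = 900,
                                    n_slices = 17L, z_spacing = 5,
                                    pixel_size = 2, noise_sd = 0.03,
                                    seed = 1L) {
  stopifnot(body_radius > 0,
            all(protrusion_lengths > body_radius + protrusion_width / 2),
            all(disseminated_distances > body_radius),
            n_slices >= 15L, z_spacing > 0, pixel_size > 0, noise_sd >= 0)
  structure(
    list(body_radius = body_radius,
         protrusion_lengths = protrusion_lengths,
         protrusion_width = protrusion_width,
         disseminated_distances = disseminated_distances,
         disseminated_areas = rep(disseminated_areas,
                                  length.out = length(disseminated_distances)),
         n_slices = as.integer(n_slices), z_spacing = z_spacing,
         pixel_size = pixel_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spheroid_spec"
  )
}

#' Generate a synthetic spheroid z-stack with ground truth
#'
#' @param spec A [synthetic_spheroid_spec()].
#' @param spheroid_id,clone_id Identifiers.
#' @return A list with `stack` (a [zstack()]) and `truth` (list: n_p,
#'   protrusion_lengths, n_c, disseminated_distances, disseminated_areas,
#'   cross_section_area_um2 of the planted central cross-section, and the
#'   planted body centroid in um).
#' @export
generate_spheroid_stack <- function(spec, spheroid_id = "synthetic",
                                    clone_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spheroid_spec"))
  ps <- spec$pixel_size
  R <- spec$body_radius
  n_p <- length(spec$protrusion_lengths)
  n_c <- length(spec$disseminated_distances)
  blob_r <- sqrt(spec$disseminated_areas / pi)
  reach <- max(R, spec$protrusion_lengths,
               spec$disseminated_distances + blob_r)
  side_um <- 2 * reach + 60
  side_px <- ceiling(side_um / ps)
  cen <- c(side_um, side_um) / 2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  # angular layout: all planted structures share one set of equally spaced
  # directions (random global offset); arms take evenly spread slots and
  # blobs the remaining ones, so structures interleave
  k_dir <- max(1L, n_p + n_c)
  off <- stats::runif(1, 0, 2 * pi)
  slots <- off + (seq_len(k_dir) - 1L) * 2 * pi / k_dir
  idx_p <- if (n_p > 0L) floor((seq_len(n_p) - 1L) * k_dir / n_p) + 1L
           else integer()
  ang_p <- slots[idx_p]
  ang_c <- slots[setdiff(seq_len(k_dir), idx_p)][seq_len(n_c)]
  if (n_p > 0L && n_c > 0L) {
    # overlap guard: blob must clear every capsule by a margin
    for (i in seq_len(n_c)) {
      bx <- cen + spec$disseminated_distances[i] * c(cos(ang_c[i]), sin(ang_c[i]))
      for (j in seq_len(n_p)) {
        tip <- cen + spec$protrusion_lengths[j] * c(cos(ang_p[j]), sin(ang_p[j]))
        d <- point_segment_dist(bx, cen, tip)
        if (d < blob_r[i] + spec$protrusion_width / 2 + 5)
          stop("overlapping planted structures: blob ", i,
               " intersects protrusion ", j)
      }
    }
  }

  xc <- (col(matrix(0, side_px, side_px)) - 1) * ps
  yc <- (row(matrix(0, side_px, side_px)) - 1) * ps
  z_mid <- (spec$n_slices + 1) / 2
  arr <- array(0, dim = c(side_px, side_px, spec$n_slices))
  d_cen <- sqrt((xc - cen[1])^2 + (yc - cen[2])^2)

  # the capsule segment stops half a width short of the planted length so
  # that its hemispherical tip cap ends exactly at tip-to-centroid = L
  hw <- spec$protrusion_width / 2
  arm_mask <- matrix(FALSE, side_px, side_px)
  if (n_p > 0L) {
    for (j in seq_len(n_p)) {
      tip <- cen + (spec$protrusion_lengths[j] - hw) *
        c(cos(ang_p[j]), sin(ang_p[j]))
      arm_mask <- arm_mask | capsule_mask(xc, yc, cen, tip, hw)
    }
  }
  blob_mask <- matrix(FALSE, side_px, side_px)
  if (n_c > 0L) {
    for (i in seq_len(n_c)) {
      bx <- cen + spec$disseminated_distances[i] * c(cos(ang_c[i]), sin(ang_c[i]))
      blob_mask <- blob_mask |
        ((xc - bx[1])^2 + (yc - bx[2])^2 <= blob_r[i]^2)
    }
  }

  for (k in seq_len(spec$n_slices)) {
    dz <- abs(k - z_mid) * spec$z_spacing
    fg <- matrix(FALSE, side_px, side_px)
    if (dz < R) fg <- fg | (d_cen <= sqrt(R^2 - dz^2))
    if (dz <= 15) fg <- fg | arm_mask       # arms span the central slices
    if (dz <= 10) fg <- fg | blob_mask      # blobs span the central slices
    slice <- ifelse(fg, 0.8, 0.05)
    if (spec$noise_sd > 0)
      slice <- slice + stats::rnorm(length(slice), 0, spec$noise_sd)
    arr[, , k] <- pmin(1, pmax(0, slice))
  }

  # analytic planted central cross-section: body disc + arm area beyond the
  # body (capsule stem outside the disc + hemispherical tip cap) + blobs
  arm_extra <- if (n_p > 0L) {
    sum(spec$protrusion_width * (spec$protrusion_lengths - hw - R) +
          pi * hw^2 / 2)
  } else 0
  truth <- list(
    n_p = n_p,
    protrusion_lengths = spec$protrusion_lengths,
    n_c = n_c,
    disseminated_distances = spec$disseminated_distances,
    disseminated_areas = spec$disseminated_areas,
    cross_section_area_um2 = pi * R^2 + arm_extra,
    body_centroid_um = cen
  )
  list(stack = zstack(arr, spec$z_spacing, ps, spheroid_id = spheroid_id,
                      clone_id = clone_id),
       truth = truth)
}

capsule_mask <- function(xc, yc, a, b, half_width) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((xc - a[1]) * ab[1] + (yc - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- xc - (a[1] + t * ab[1])
  dy <- yc - (a[2] + t * ab[2])
  dx^2 + dy^2 <= half_width^2
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}
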