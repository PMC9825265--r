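#' Maximum-intensity projection of a spheroid z-stack
#'
#' Selects a window of slices (default 75 um, i.e. fifteen 5-um slices)
#' from the centre of the spheroid and max-projects them along z. The
#' centre is either a given slice index or chosen automatically as the
#' slice with the largest foreground after a provisional Otsu threshold.
#'
#' @param stack A [zstack()].
#' @param window Window height in micrometres (default 75).
#' @param center Slice index at the window centre, or `"auto"`.
#' @return A numeric matrix (the projection) with attribute `slices_used`.
#' @export
project_stack <- function(stack, window = 75, center = "auto") {
  stopifnot(inherits(stack, "zstack"))
  nz <- dim(stack$slices)[3]
  n_window <- max(1L, round(window / stack$z_spacing))
  if (nz < n_window)
    stop("stack spans less than the projection window (", nz, " < ",
         n_window, " slices)")
  if (identical(center, "auto")) {
    fg <- vapply(seq_len(nz), function(k) {
      s <- stack$slices[, , k]
      thr <- otsu_threshold(s)
      sum(s > thr)
    }, 0)
    center <- which.max(fg)
  }
  half <- (n_window - 1L) %/% 2L
  lo <- center - half
  hi <- lo + n_window - 1L
  if (lo < 1L) { lo <- 1L; hi <- n_window }
  if (hi > nz) { hi <- nz; lo <- nz - n_window + 1L }
  proj <- apply(stack$slices[, , lo:hi, drop = FALSE], c(1, 2), max)
  attr(proj, "slices_used") <- lo:hi
  proj
}

# Otsu threshold on [min, max]-normalized intensities
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xn <- (x - rng[1]) / diff(rng)
  t <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  rng[1] + t * diff(rng)
}

#' Binarize a projected spheroid image
#'
#' Global Otsu threshold, removal of connected components smaller than
#' `min_area`, and hole filling within the remaining foreground.
#'
#' @param projection Numeric matrix from [project_stack()].
#' @param pixel_size Micrometres per pixel.
#' @param min_area Smallest retained component, um^2 (default 50).
#' @param threshold Optional fixed intensity threshold overriding Otsu.
#' @return A logical matrix.
#' @export
binarize <- function(projection, pixel_size, min_area = 50,
                     threshold = NULL) {
  stopifnot(is.matrix(projection), pixel_size > 0)
  if (diff(range(projection)) == 0) stop("binarize: blank image")
  thr <- if (is.null(threshold)) otsu_threshold(projection) else threshold
  mask <- projection > thr
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * pixel_size^2 >= min_area)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  filled <- EBImage::fillHull(EBImage::bwlabel(mask)) > 0
  matrix(as.logical(filled), nrow(mask), ncol(mask))
}

#' Shape of the spheroid main body
#'
#' The main body is the largest connected component of the mask. Area is
#' the pixel count scaled to um^2, circularity is 4*pi*A/P^2 with the
#' same contour perimeter estimator used for single cells, and solidity
#' is area over the pixelated convex hull area.
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size Micrometres per pixel.
#' @return One-row tibble: `area_um2`, `circularity`, `solidity`, plus the
#'   body centroid `x_um`, `y_um`.
#' @export
measure_spheroid <- function(mask, pixel_size) {
  body <- main_body(mask)
  if (is.null(body)) stop("measure_spheroid: empty mask")
  ps <- pixel_size
  idx <- which(body)
  rows <- (idx - 1L) %% nrow(body) + 1L
  cols <- (idx - 1L) %/% nrow(body) + 1L
  a_px <- length(idx)
  perim <- contour_perimeter(EBImage::ocontour(body * 1L)[[1]]) * ps
  area <- a_px * ps^2
  hull_px <- convex_hull_pixel_area(rows, cols)
  tibble::tibble(
    area_um2 = area,
    circularity = min(1, 4 * pi * area / perim^2),
    solidity = min(1, a_px / hull_px),
    x_um = mean(cols - 1) * ps,
    y_um = mean(rows - 1) * ps
  )
}

# largest connected component of a logical mask (NULL when empty)
main_body <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  matrix(lab == which.max(sizes), nrow(mask), ncol(mask))
}

# pixel-covered area of the convex hull: shoelace over hull vertices
# (pixel centres) plus the boundary half-pixel band (Pick-style correction)
convex_hull_pixel_area <- function(rows, cols) {
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2
  per <- sum(sqrt((xs - x)^2 + (ys - y)^2))
  area + per / 2 + 1
}

#' Detect spheroid protrusions
#'
#' The body core is the morphological opening of the main body with a disc
#' of `core_radius` (default 0.8 x the body's equivalent radius), computed
#' exactly via the Euclidean distance transform. Protrusion candidates are
#' connected components of body minus core that touch the core and extend
#' radially by at least `min_length`; the recorded length of each is the
#' maximum distance from its pixels to the body centroid (tip-to-centroid).
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size Micrometres per pixel.
#' @param core_radius Opening radius in um, or `NULL` for the default.
#' @param min_length Minimum radial extent of a counted protrusion, um
#'   (default 20).
#' @return A list: `n_p`, `lengths_um` (sorted decreasing), `core`
#'   (logical matrix), `centroid_um`.
#' @export
detect_protrusions <- function(mask, pixel_size, core_radius = NULL,
                               min_length = 20) {
  body <- main_body(mask)
  if (is.null(body)) stop("detect_protrusions: empty mask")
  ps <- pixel_size
  if (is.null(core_radius)) {
    core_radius <- 0.8 * sqrt(sum(body) * ps^2 / pi)
  }
  r_px <- core_radius / ps
  core <- euclidean_opening(body, r_px)
  if (!any(core)) stop("detect_protrusions: core is empty; reduce core_radius")
  # spheroid centroid from the core: protrusion mass would otherwise drag
  # the body centroid towards the longest arms and bias every length
  cen <- mask_centroid_um(core, ps)
  residue <- body & !core
  lab <- EBImage::bwlabel(residue)
  k <- max(lab)
  lengths <- numeric(0)
  if (k > 0L) {
    touching <- components_touching(lab, core)
    for (l in seq_len(k)) {
      if (!touching[l]) next
      li <- which(lab == l)
      lr <- (li - 1L) %% nrow(lab) + 1L
      lc <- (li - 1L) %/% nrow(lab) + 1L
      d <- sqrt(((lc - 1) * ps - cen[1])^2 + ((lr - 1) * ps - cen[2])^2)
      if (max(d) - min(d) >= min_length) lengths <- c(lengths, max(d))
    }
  }
  list(n_p = length(lengths), lengths_um = sort(lengths, decreasing = TRUE),
       core = core, centroid_um = cen)
}

# centroid of a logical mask in (x, y) micrometres, 0-based pixel centres
mask_centroid_um <- function(mask, ps) {
  idx <- which(mask)
  c(mean((idx - 1L) %/% nrow(mask)), mean((idx - 1L) %% nrow(mask))) * ps
}

# exact Euclidean morphological opening: erosion = distance-to-background
# > r, dilation = within r of the eroded set
euclidean_opening <- function(mask, r_px) {
  er <- EBImage::distmap(mask * 1L) > r_px
  if (!any(er)) return(er)
  dl <- EBImage::distmap((!er) * 1L) <= r_px
  matrix(as.logical(dl), nrow(mask), ncol(mask))
}

# which labels of `lab` have a pixel 8-adjacent to `core`
components_touching <- function(lab, core) {
  grown <- EBImage::dilate(core * 1L, EBImage::makeBrush(3L, "box")) > 0
  k <- max(lab)
  touch <- logical(k)
  hits <- lab[grown & lab > 0]
  if (length(hits)) touch[unique(hits)] <- TRUE
  touch
}

#' Detect disseminated regions around a spheroid
#'
#' Counts foreground components disconnected from the main body (cells or
#' cell groups that migrated away), with their areas and
#' centroid-to-centroid distances from the main body.
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size Micrometres per pixel.
#' @param min_area Smallest counted region, um^2 (default 50).
#' @param centroid_um Optional spheroid centroid (x, y in um) to measure
#'   distances from; by default the centroid of the opened main body (see
#'   [detect_protrusions()]), so distances are not biased by protrusion
#'   mass.
#' @return A list: `n_c`, `areas_um2`, `distances_um` (aligned), and
#'   `regions` (tibble with centroids).
#' @export
detect_dissemination <- function(mask, pixel_size, min_area = 50,
                                 centroid_um = NULL) {
  body <- main_body(mask)
  if (is.null(body)) stop("detect_dissemination: empty mask")
  ps <- pixel_size
  cen <- if (is.null(centroid_um)) {
    core <- euclidean_opening(body, 0.8 * sqrt(sum(body) / pi))
    mask_centroid_um(if (any(core)) core else body, ps)
  } else centroid_um
  lab <- EBImage::bwlabel(mask)
  body_label <- lab[which(body)[1]]
  k <- max(lab)
  out <- tibble::tibble(region = integer(), area_um2 = double(),
                        x_um = double(), y_um = double(),
                        distance_um = double())
  for (l in seq_len(k)) {
    if (l == body_label) next
    li <- which(lab == l)
    a <- length(li) * ps^2
    if (a < min_area) next
    x <- mean((li - 1L) %/% nrow(lab)) * ps
    y <- mean((li - 1L) %% nrow(lab)) * ps
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = l, area_um2 = a, x_um = x, y_um = y,
      distance_um = sqrt((x - cen[1])^2 + (y - cen[2])^2)))
  }
  list(n_c = nrow(out), areas_um2 = out$area_um2,
       distances_um = out$distance_um, regions = out)
}

#' Full spheroid measurement from a z-stack
#'
#' Chains [project_stack()], [binarize()], [measure_spheroid()],
#' [detect_protrusions()] and [detect_dissemination()].
#'
#' @param stack A [zstack()].
#' @param window,center Passed to [project_stack()].
#' @param min_area,threshold Passed to [binarize()] /
#'   [detect_dissemination()].
#' @param core_radius,min_length Passed to [detect_protrusions()].
#' @return One-row tibble: spheroid_id, clone_id, area_um2, circularity,
#'   solidity, n_p, avg_p, max_p, n_c, avg_c, max_c (lengths/distances in
#'   um; avg/max are NA when the count is 0... see Details) plus list
#'   columns `protrusion_lengths` and `region_distances`.
#' @details `avg_p`/`max_p` (`avg_c`/`max_c`) are 0 when no protrusion
#'   (region) exists: an absent feature contributes no invasive length.
#' @export
measure_spheroid_stack <- function(stack, window = 75, center = "auto",
                                   min_area = 50, threshold = NULL,
                                   core_radius = NULL, min_length = 20) {
  proj <- project_stack(stack, window = window, center = center)
  mask <- binarize(proj, stack$pixel_size, min_area = min_area,
                   threshold = threshold)
  shape <- measure_spheroid(mask, stack$pixel_size)
  pro <- detect_protrusions(mask, stack$pixel_size,
                            core_radius = core_radius,
                            min_length = min_length)
  dis <- detect_dissemination(mask, stack$pixel_size, min_area = min_area,
                              centroid_um = pro$centroid_um)
  tibble::tibble(
    spheroid_id = stack$spheroid_id, clone_id = stack$clone_id,
    area_um2 = shape$area_um2, circularity = shape$circularity,
    solidity = shape$solidity,
    n_p = pro$n_p,
    avg_p = if (pro$n_p) mean(pro$lengths_um) else 0,
    max_p = if (pro$n_p) max(pro$lengths_um) else 0,
    n_c = dis$n_c,
    avg_c = if (dis$n_c) mean(dis$distances_um) else 0,
    max_c = if (dis$n_c) max(dis$distances_um) else 0,
    protrusion_lengths = list(pro$lengths_um),
    region_distances = list(dis$distances_um)
  )
}

#' Composite 3D invasion score per clone
#'
#' The six invasion metrics (protrusion count, mean and max length;
#' disseminated count, mean and max distance) are averaged over replicate
#' spheroids of each clone, min-max normalized to [0, 1] across the clone
#' set (0 and 1 are the minimum and maximum measured values), and averaged
#' with equal weights:
#' invasion3D = (n_p + n_c + avg_p + avg_c + max_p + max_c) / 6 on the
#' normalized scale. A metric constant across clones is defined as 0 for
#' every clone, with a warning.
#'
#' @param measurements Data frame of spheroid rows (one per replicate)
#'   with `clone_id` and the six metric columns, e.g. from
#'   [measure_spheroid_stack()].
#' @return Tibble: one row per clone with `invasion3D`, the six normalized
#'   inputs (suffix `_norm`), and the per-metric normalization bounds as
#'   attribute `bounds`.
#' @export
invasion_score <- function(measurements) {
  metrics <- c("n_p", "avg_p", "max_p", "n_c", "avg_c", "max_c")
  stopifnot(is.data.frame(measurements),
            all(c("clone_id", metrics) %in% names(measurements)))
  per_clone <- dplyr::summarise(
    dplyr::group_by(measurements, .data$clone_id),
    dplyr::across(dplyr::all_of(metrics), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  if (nrow(per_clone) < 2L)
    stop("invasion_score: need >= 2 clones to normalize")
  bounds <- tibble::tibble(
    metric = metrics,
    min = vapply(metrics, function(m) min(per_clone[[m]]), 0),
    max = vapply(metrics, function(m) max(per_clone[[m]]), 0)
  )
  norm <- per_clone["clone_id"]
  for (m in metrics) {
    lo <- min(per_clone[[m]]); hi <- max(per_clone[[m]])
    if (hi == lo) {
      warning("metric '", m, "' is constant across clones; normalized to 0")
      norm[[paste0(m, "_norm")]] <- 0
    } else {
      norm[[paste0(m, "_norm")]] <- (per_clone[[m]] - lo) / (hi - lo)
    }
  }
  norm$invasion3D <- rowMeans(norm[, paste0(metrics, "_norm")])
  out <- dplyr::left_join(per_clone, norm, by = "clone_id")
  attr(out, "bounds") <- bounds
  out
}

#' Plot a spheroid mask with detected features
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size Micrometres per pixel.
#' @param core_radius,min_length,min_area Passed to the detectors.
#' @return A ggplot object showing body, core, protrusions and
#'   disseminated regions.
#' @export
plot_spheroid_mask <- function(mask, pixel_size, core_radius = NULL,
                               min_length = 20, min_area = 50) {
  pro <- detect_protrusions(mask, pixel_size, core_radius = core_radius,
                            min_length = min_length)
  body <- main_body(mask)
  df <- tibble::tibble(
    x = (which(mask) - 1L) %/% nrow(mask) * pixel_size,
    y = (which(mask) - 1L) %% nrow(mask) * pixel_size,
    part = dplyr::case_when(
      !body[which(mask)] ~ "disseminated",
      pro$core[which(mask)] ~ "core",
      TRUE ~ "protrusion/rim"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$part)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = NULL)
}
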