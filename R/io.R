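#' Construct a label image
#'
#' A label image is the unit of 2D input: an integer matrix of instance
#' labels (0 = background) together with its physical pixel size. Labels are
#' relabeled at construction to consecutive positive integers (ascending
#' original id order), so downstream code can index arrays by label.
#'
#' Coordinate convention: pixels are addressed (row, col), 0-based in
#' physical terms; the centre of pixel (i, j) sits at
#' (x, y) = ((j - 1) * pixel_size, (i - 1) * pixel_size) micrometres for
#' 1-based R indices.
#'
#' @param pixels Integer matrix of non-negative labels; 0 is background.
#' @param pixel_size Micrometres per pixel (isotropic), > 0.
#' @param image_id,clone_id Opaque identifier strings.
#' @param time_h Hours since seeding (optional; density, not time, is the
#'   primary independent variable downstream).
#' @return An object of class `label_image`.
#' @export
label_image <- function(pixels, pixel_size, image_id = "img",
                        clone_id = NA_character_, time_h = NA_real_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a 2D matrix")
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  if (any(pixels < 0)) stop("labels must be non-negative integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  storage.mode(pixels) <- "integer"
  ids <- sort(unique(pixels[pixels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- pixels > 0L
    pixels[pos] <- lut[pixels[pos]]
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         image_id = image_id, clone_id = clone_id, time_h = time_h),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %s: %d x %d px @ %.3g um/px, %d cells\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              n_cells(x)))
  invisible(x)
}

#' Number of labelled cells in a label image
#' @param img A `label_image`.
#' @return Integer count of distinct positive labels.
#' @export
n_cells <- function(img) {
  stopifnot(inherits(img, "label_image"))
  length(unique(img$pixels[img$pixels > 0L]))
}

#' Read a 2D label image from TIFF
#'
#' Reads an integer (or integer-valued) TIFF and relabels labels to
#' consecutive positive integers preserving distinctness.
#'
#' @param path Path to a 2D TIFF file.
#' @inheritParams label_image
#' @return A `label_image`.
#' @export
read_label_image <- function(path, pixel_size, image_id = basename(path),
                             clone_id = NA_character_, time_h = NA_real_) {
  if (!file.exists(path)) stop("cannot read label image: ", path)
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e) {
    stop("cannot read label image '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L)
      stop("label image must be 2D (single channel): ", path)
    px <- px[, , 1L]
  }
  if (length(dim(px)) != 2L) stop("label image must be 2D: ", path)
  if (any(px < 0)) stop("label image contains negative values: ", path)
  label_image(px, pixel_size, image_id = image_id,
              clone_id = clone_id, time_h = time_h)
}

#' Write a label image as 16-bit TIFF
#' @param img A `label_image` (at most 65535 labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  stopifnot(inherits(img, "label_image"))
  mx <- max(img$pixels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit")
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Construct a z-stack
#'
#' Ordered fluorescence slices with known z-spacing, as produced by confocal
#' imaging of a spheroid (typically 5 um increments).
#'
#' @param slices 3D numeric array (rows x cols x slices) or list of equally
#'   sized matrices.
#' @param z_spacing Micrometres between consecutive slices, > 0.
#' @param pixel_size Micrometres per pixel in-plane, > 0.
#' @param spheroid_id,clone_id Identifier strings.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, z_spacing, pixel_size, spheroid_id = "sph",
                   clone_id = NA_character_) {
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L) stop("all slices must share dimensions")
    slices <- array(unlist(slices), dim = c(dims[[1]], length(slices)))
  }
  if (length(dim(slices)) != 3L) stop("`slices` must be a 3D array")
  if (z_spacing <= 0 || pixel_size <= 0)
    stop("z_spacing and pixel_size must be positive")
  structure(
    list(slices = slices, z_spacing = as.numeric(z_spacing),
         pixel_size = as.numeric(pixel_size), spheroid_id = spheroid_id,
         clone_id = clone_id),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<zstack> %s: %d x %d px, %d slices @ %g um, %.3g um/px\n",
              x$spheroid_id, d[1], d[2], d[3], x$z_spacing, x$pixel_size))
  invisible(x)
}

#' Read a multi-page TIFF as a z-stack
#' @param path Path to a multi-page TIFF.
#' @inheritParams zstack
#' @return A `zstack`.
#' @export
read_zstack <- function(path, z_spacing, pixel_size,
                        spheroid_id = basename(path),
                        clone_id = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p
  })
  zstack(pages, z_spacing, pixel_size, spheroid_id = spheroid_id,
         clone_id = clone_id)
}

#' Write a z-stack as multi-page TIFF
#' @param stack A `zstack`; intensities are rescaled to [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  arr <- stack$slices
  rng <- range(arr)
  if (diff(rng) > 0) arr <- (arr - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a cell network to GraphML
#'
#' Persists nodes (with centroid in micrometres and area in square
#' micrometres) and the adjacency edge list. The file round-trips
#' losslessly through [read_network()].
#'
#' @param net A `cell_network`.
#' @param path Output path (GraphML).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cell_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Read a cell network from GraphML
#' @param path Path written by [write_network()].
#' @return A `cell_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  new_cell_network(g)
}
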