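test_that("projection takes the max over the central window", {
  # slice k has constant intensity k/20: projection = max over window
  arr <- array(rep((1:20) / 20, each = 64), dim = c(8, 8, 20))
  st <- zstack(arr, z_spacing = 5, pixel_size = 2)
  proj <- project_stack(st, window = 75, center = 10)
  used <- attr(proj, "slices_used")
  expect_identical(length(used), 15L)
  expect_equal(unique(as.vector(proj)), max(used) / 20)
  # a 15-slice stack at 5 um spacing uses exactly all slices
  st15 <- zstack(array(runif(8 * 8 * 15), dim = c(8, 8, 15)),
                 z_spacing = 5, pixel_size = 2)
  expect_identical(attr(project_stack(st15), "slices_used"), 1:15)
  expect_error(project_stack(zstack(array(1, dim = c(4, 4, 5)),
                                    5, 2), window = 75), "window")
})

test_that("binarization recovers a separable two-level image exactly", {
  img <- matrix(10, 40, 40)
  img[10:30, 10:30] <- 200
  mask <- binarize(img, pixel_size = 2)
  expect_identical(mask, matrix(row(img) %in% 10:30 & col(img) %in% 10:30,
                                40, 40))
  expect_error(binarize(matrix(5, 10, 10), 1), "blank")
  # sub-min_area specks are removed
  speck <- img
  speck[1, 1] <- 200
  expect_identical(sum(binarize(speck, pixel_size = 2)), 21L * 21L)
})

test_that("spheroid shape: disc and star fixtures", {
  m <- matrix(FALSE, 240, 240)
  m[(row(m) - 120)^2 + (col(m) - 120)^2 <= 100^2] <- TRUE
  res <- measure_spheroid(m, pixel_size = 2)  # radius 200 um
  expect_lt(abs(res$area_um2 - pi * 200^2) / (pi * 200^2), 0.02)
  expect_gte(res$solidity, 0.98)
  expect_lte(res$solidity, 1)
  expect_gt(res$circularity, 0.95)

  # 4-arm star: solidity well below a convex shape
  star <- matrix(FALSE, 300, 300)
  star[(row(star) - 150)^2 + (col(star) - 150)^2 <= 50^2] <- TRUE
  star[140:160, 10:290] <- TRUE
  star[10:290, 140:160] <- TRUE
  res_star <- measure_spheroid(star, pixel_size = 2)
  expect_lt(res_star$solidity, 0.8)
})

test_that("protrusion detection: null disc, planted star, short-arm filter", {
  sph0 <- generate_spheroid_stack(synthetic_spheroid_spec(seed = 5))
  m0 <- measure_spheroid_stack(sph0$stack)
  expect_identical(m0$n_p, 0L)
  expect_identical(m0$n_c, 0L)
  expect_equal(m0$max_p, 0)

  spec <- synthetic_spheroid_spec(
    protrusion_lengths = c(250, 250, 300, 300), seed = 6)
  sph <- generate_spheroid_stack(spec)
  m <- measure_spheroid_stack(sph$stack)
  expect_identical(m$n_p, 4L)
  expect_lt(abs(m$max_p - 300), 2 * sph$stack$pixel_size)
  expect_lt(max(abs(sort(unlist(m$protrusion_lengths)) - sort(spec$protrusion_lengths))),
            2 * sph$stack$pixel_size)

  # an arm whose radial extent is below min_length is not counted
  spec_short <- synthetic_spheroid_spec(
    protrusion_lengths = c(216, 300), seed = 7)  # extents ~16 and ~100 um
  sph_s <- generate_spheroid_stack(spec_short)
  m_s <- measure_spheroid_stack(sph_s$stack, min_length = 20)
  expect_identical(m_s$n_p, 1L)
})

test_that("dissemination detection: counts, distances, min-area filter", {
  spec <- synthetic_spheroid_spec(
    disseminated_distances = c(260, 300, 340),
    disseminated_areas = c(900, 900, 900), seed = 8)
  sph <- generate_spheroid_stack(spec)
  m <- measure_spheroid_stack(sph$stack)
  expect_identical(m$n_c, 3L)
  expect_equal(m$avg_c, 300, tolerance = 2 * sph$stack$pixel_size / 300)
  expect_lt(max(abs(sort(unlist(m$region_distances)) -
                      sort(spec$disseminated_distances))),
            2 * sph$stack$pixel_size)

  # a blob below min_area is excluded
  proj <- project_stack(sph$stack)
  mask <- binarize(proj, sph$stack$pixel_size)
  d_all <- detect_dissemination(mask, sph$stack$pixel_size, min_area = 50)
  d_strict <- detect_dissemination(mask, sph$stack$pixel_size,
                                   min_area = 2000)
  expect_identical(d_all$n_c, 3L)
  expect_identical(d_strict$n_c, 0L)
})

test_that("protrusions and disseminated regions partition non-core foreground", {
  spec <- synthetic_spheroid_spec(protrusion_lengths = c(260, 320),
                                  disseminated_distances = c(280, 360),
                                  seed = 12)
  sph <- generate_spheroid_stack(spec)
  proj <- project_stack(sph$stack)
  mask <- binarize(proj, sph$stack$pixel_size)
  pro <- detect_protrusions(mask, sph$stack$pixel_size)
  dis <- detect_dissemination(mask, sph$stack$pixel_size,
                              centroid_um = pro$centroid_um)
  body <- mask & !is.na(mask)
  # no pixel is both in the core and in a disseminated region, and every
  # foreground pixel is core, body residue, or disseminated
  lab <- EBImage::bwlabel(mask)
  body_label <- lab[which(pro$core)[1]]
  dis_px <- sum(lab > 0 & lab != body_label)
  expect_identical(sum(mask), sum(pro$core) + sum(mask & lab == body_label & !pro$core) + dis_px)
})

test_that("invasion score is the mean of min-max normalized metrics", {
  meas <- tibble::tribble(
    ~clone_id, ~n_p, ~avg_p, ~max_p, ~n_c, ~avg_c, ~max_c,
    "low",    0,    0,      0,      0,    0,      0,
    "mid",    2,  100,    150,      1,  200,    200,
    "high",   4,  200,    300,      3,  400,    500)
  inv <- invasion_score(meas)
  expect_equal(inv$invasion3D[inv$clone_id == "low"], 0)
  expect_equal(inv$invasion3D[inv$clone_id == "high"], 1)
  expect_equal(inv$invasion3D[inv$clone_id == "mid"],
               mean(c(2 / 4, 100 / 200, 150 / 300, 1 / 3, 200 / 400,
                      200 / 500)))
  # replicates are averaged per clone before normalization
  reps <- dplyr::bind_rows(meas, dplyr::mutate(meas, n_p = n_p + 2))
  inv_r <- invasion_score(reps)
  expect_equal(inv_r$n_p[match(meas$clone_id, inv_r$clone_id)],
               meas$n_p + 1)
  # invariance to uniform affine rescaling of one metric
  scaled <- dplyr::mutate(meas, avg_c = avg_c * 3 + 10)
  expect_equal(invasion_score(scaled)$invasion3D, inv$invasion3D)
  # constant metric normalizes to 0 with a warning
  const <- dplyr::mutate(meas, max_c = 7)
  expect_warning(inv_c <- invasion_score(const), "constant")
  expect_true(all(inv_c$max_c_norm == 0))
})
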