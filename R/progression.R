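#' Fit a polynomial density trend to one property
#'
#' Least-squares polynomial of `value` on `confluency`; density, not time,
#' is the independent variable of a morphological progression.
#'
#' @param data A data frame with columns `confluency` and `value` (or pass
#'   two numeric vectors via `confluency` and `value`).
#' @param degree Polynomial degree (default 2).
#' @return A list of class `progression_fit`: `coefficients` (ascending
#'   powers), `residual_variance` (df-adjusted), `std_errors`, `n`,
#'   `range` of observed confluency.
#' @export
fit_progression <- function(data, degree = 2L) {
  stopifnot(is.data.frame(data),
            all(c("confluency", "value") %in% names(data)))
  x <- data$confluency
  y <- data$value
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < degree + 1L)
    stop("fit_progression: need >= degree+1 distinct confluency values")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- unname(stats::coef(fit))
  # suppress the "essentially perfect fit" note for noiseless fixtures
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit)))))
  rv <- if (fit$df.residual > 0) {
    sum(stats::residuals(fit)^2) / fit$df.residual
  } else 0
  structure(
    list(coefficients = cf, residual_variance = rv, std_errors = se,
         n = length(x), degree = as.integer(degree), range = range(x)),
    class = "progression_fit"
  )
}

#' Evaluate a progression fit at given confluencies
#' @param fit A `progression_fit`.
#' @param confluency Numeric vector of densities.
#' @return Fitted values.
#' @export
predict_progression <- function(fit, confluency) {
  stopifnot(inherits(fit, "progression_fit"))
  polynomial_eval(fit$coefficients, confluency)
}

#' Assemble a clone's morphological progression
#'
#' Takes tidy snapshot rows (one row per image: `clone_id`, `confluency`,
#' property columns; see [tidy.population_snapshot()] and
#' [network_metrics()]) and fits a per-property polynomial trend against
#' confluency.
#'
#' @param data Data frame of snapshot rows for a single clone.
#' @param properties Character vector of property columns to fit; default
#'   all numeric columns except `confluency`, `time_h` and `n_cells`.
#' @param degree Polynomial degree (default 2).
#' @return An object of class `clone_progression`: `clone_id`, `points`,
#'   `degree`, `fits` (named list of `progression_fit`; properties with
#'   too few points are skipped with a warning).
#' @export
clone_progression <- function(data, properties = NULL, degree = 2L) {
  stopifnot(is.data.frame(data), "confluency" %in% names(data))
  clone_id <- if ("clone_id" %in% names(data)) {
    unique(data$clone_id)
  } else "clone"
  if (length(clone_id) != 1L)
    stop("clone_progression: data must belong to a single clone")
  if (is.null(properties)) {
    num <- vapply(data, is.numeric, TRUE)
    properties <- setdiff(names(data)[num],
                          c("confluency", "time_h", "n_cells"))
  }
  fits <- list()
  for (p in properties) {
    f <- tryCatch(
      fit_progression(
        data.frame(confluency = data$confluency, value = data[[p]]),
        degree = degree),
      error = function(e) NULL)
    if (is.null(f)) {
      warning("clone ", clone_id, ": property '", p,
              "' has too few points; fit skipped")
    } else {
      fits[[p]] <- f
    }
  }
  structure(
    list(clone_id = clone_id, points = tibble::as_tibble(data),
         degree = as.integer(degree), fits = fits),
    class = "clone_progression"
  )
}

#' @export
print.clone_progression <- function(x, ...) {
  cat(sprintf("<clone_progression> %s: %d snapshots, %d fitted properties (degree %d)\n",
              x$clone_id, nrow(x$points), length(x$fits), x$degree))
  invisible(x)
}

#' Tidy a clone progression's fits
#' @param x A `clone_progression`.
#' @param ... Unused.
#' @return Tibble: property, term (power), estimate, std.error,
#'   residual_variance, n.
#' @export
tidy.clone_progression <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, p) {
    tibble::tibble(
      property = p,
      term = paste0("confluency^", seq_along(f$coefficients) - 1L),
      estimate = f$coefficients,
      std.error = f$std_errors,
      residual_variance = f$residual_variance,
      n = f$n
    )
  })
}

#' Growth variables: anchor evaluations of a clone's fitted trends
#'
#' Each fitted property polynomial is evaluated at low / mid / high
#' confluency anchors (default 0.15, 0.40, 0.70), producing one scalar per
#' property per anchor with suffixes `_l`, `_m`, `_h`. These are the
#' per-clone feature vector used for clustering and correlation. Anchors
#' outside the observed confluency range are evaluated anyway but flagged
#' as extrapolated.
#'
#' @param prog A [clone_progression()].
#' @param anchors Numeric confluency anchors, named or in low/mid/high
#'   order.
#' @return A one-row tibble: `clone_id` plus `<property>_<l|m|h>` columns,
#'   with an `extrapolated` attribute naming flagged entries.
#' @export
growth_variables <- function(prog, anchors = c(l = 0.15, m = 0.40, h = 0.70)) {
  stopifnot(inherits(prog, "clone_progression"))
  if (is.null(names(anchors)))
    names(anchors) <- c("l", "m", "h")[seq_along(anchors)]
  if (!length(prog$fits)) stop("growth_variables: no fitted properties")
  vals <- list(clone_id = prog$clone_id)
  extrapolated <- character(0)
  for (p in names(prog$fits)) {
    f <- prog$fits[[p]]
    for (a in names(anchors)) {
      nm <- paste0(p, "_", a)
      vals[[nm]] <- predict_progression(f, anchors[[a]])
      if (anchors[[a]] < f$range[1] || anchors[[a]] > f$range[2])
        extrapolated <- c(extrapolated, nm)
    }
  }
  out <- tibble::as_tibble(vals)
  attr(out, "extrapolated") <- extrapolated
  out
}

#' Growth-variable table for a set of clones
#'
#' @param data Snapshot rows for several clones (must contain `clone_id`).
#' @param properties,degree,anchors Passed through per clone.
#' @return A tibble with one row per clone (union of columns; properties
#'   unfittable for a clone yield NA).
#' @export
growth_variable_table <- function(data, properties = NULL, degree = 2L,
                                  anchors = c(l = 0.15, m = 0.40, h = 0.70)) {
  stopifnot(is.data.frame(data), "clone_id" %in% names(data))
  purrr::map_dfr(split(data, data$clone_id), function(d) {
    growth_variables(
      clone_progression(d, properties = properties, degree = degree),
      anchors = anchors)
  })
}

#' Plot a clone's fitted progressions
#'
#' Observed property values against confluency with the fitted polynomial
#' overlaid, one facet per property.
#'
#' @param object A `clone_progression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_progression <- function(object, ...) {
  props <- names(object$fits)
  obs <- tidyr::pivot_longer(
    object$points[, c("confluency", props), drop = FALSE],
    dplyr::all_of(props), names_to = "property")
  grid <- seq(min(object$points$confluency), max(object$points$confluency),
              length.out = 100)
  fitted <- purrr::imap_dfr(object$fits, function(f, p) {
    tibble::tibble(confluency = grid, property = p,
                   value = predict_progression(f, grid))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$confluency, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "confluency", y = NULL,
                  title = paste("Morphological progression:", object$clone_id))
}
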