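#' Hotelling T-squared confidence ellipse for 2-D scores
#'
#' For one class's n x 2 score matrix, the `confidence`-level Hotelling
#' T-squared region is the set
#' \eqn{\{x : (x - \mu)^\top S^{-1} (x - \mu) \le c^2\}} with
#' \eqn{c^2 = \frac{2 (n - 1)}{n - 2} F_{2, n-2}(\mathrm{conf})}, using the
#' small-sample F scaling rather than the chi-squared asymptotic (class
#' sizes in this kind of design are 3-8 animals, where the chi-squared
#' region under-covers). Semi-axes are \eqn{c \sqrt{\mathrm{eig}(S)}} along
#' the eigenvectors of the sample covariance S.
#'
#' @param scores numeric n x 2 matrix of one class's scores, n >= 3.
#' @param confidence coverage level in (0, 1); default 0.98.
#' @param label class label stored in the result.
#' @return an object of class `ellipse_spec`: `label`, `center` (2-vector),
#'   `semi_axes` (major, minor), `angle` (radians of the major axis),
#'   `confidence`, `n`, plus the covariance and threshold used.
#' @export
hotelling_ellipse <- function(scores, confidence = 0.98, label = "class") {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, confidence > 0, confidence < 1)
  n <- nrow(scores)
  if (n < 3)
    stop("Hotelling ellipse needs n >= 3 samples (got ", n, ")")
  center <- colMeans(scores)
  S <- stats::cov(scores)
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) <= max(eg$values) * 1e-12 || max(eg$values) == 0)
    stop("singular score covariance for class '", label,
         "' (collinear scores); add samples or jitter")
  c2 <- 2 * (n - 1) / (n - 2) * stats::qf(confidence, 2, n - 2)
  structure(list(label = label, center = center,
                 semi_axes = sqrt(c2 * eg$values),
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                 confidence = confidence, n = n, cov = S, c2 = c2),
            class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf(
    "<ellipse_spec '%s'> n = %d, %.0f%% level, center (%.3g, %.3g), semi-axes (%.3g, %.3g)\n",
    x$label, x$n, 100 * x$confidence, x$center[1], x$center[2],
    x$semi_axes[1], x$semi_axes[2]))
  invisible(x)
}

#' Points on an ellipse boundary
#' @param spec an `ellipse_spec`.
#' @param n_points number of boundary points.
#' @return n_points x 2 matrix tracing the boundary.
#' @export
ellipse_boundary <- function(spec, n_points = 200) {
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(spec$semi_axes[1] * cos(theta),
                spec$semi_axes[2] * sin(theta))
  rot <- matrix(c(cos(spec$angle), sin(spec$angle),
                  -sin(spec$angle), cos(spec$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, spec$center, "+")
}

#' Which points fall inside an ellipse
#' @param spec an `ellipse_spec`.
#' @param points m x 2 matrix.
#' @return logical vector: Mahalanobis distance (w.r.t. the class
#'   covariance) within the T-squared threshold.
#' @export
in_ellipse <- function(spec, points) {
  points <- as.matrix(points)
  d2 <- stats::mahalanobis(points, spec$center, spec$cov)
  d2 <= spec$c2
}

#' ComDim score plot with per-class Hotelling ellipses
#'
#' Draws a 2-D scatter of the chosen component pair, one Hotelling
#' T-squared ellipse per level of `class_factor`, axes labelled with the
#' explained-variation percentages. Classes with fewer than 3 samples get
#' points but no ellipse (warning).
#'
#' @param result a `comdim_result` with >= 2 components.
#' @param metadata a `sample_metadata` covering the scored samples.
#' @param class_factor metadata factor defining the classes.
#' @param components integer pair of components to plot.
#' @param confidence ellipse confidence level; default 0.98.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param draw set `FALSE` to skip drawing and only compute the ellipses.
#' @return invisibly, a named list of `ellipse_spec` (one per class with
#'   n >= 3).
#' @export
score_plot <- function(result, metadata, class_factor,
                       components = c(1, 2), confidence = 0.98,
                       file = NULL, draw = TRUE) {
  stopifnot(inherits(result, "comdim_result"))
  if (ncol(result$scores) < max(components))
    stop("result has ", ncol(result$scores), " component(s); cannot plot ",
         paste(components, collapse = " vs "))
  sc <- result$scores[, components, drop = FALSE]
  f <- get_factor(metadata, class_factor, min_levels = 1L)[result$sample_ids]
  classes <- sort(unique(f))
  ellipses <- list()
  for (cl in classes) {
    pts <- sc[f == cl, , drop = FALSE]
    if (nrow(pts) < 3) {
      warning("class '", cl, "' has n = ", nrow(pts),
              " < 3; ellipse skipped")
      next
    }
    ellipses[[cl]] <- hotelling_ellipse(pts, confidence, label = cl)
  }
  if (draw) {
    if (!is.null(file)) {
      grDevices::png(file, width = 700, height = 700)
      on.exit(grDevices::dev.off())
    }
    bounds <- lapply(ellipses, ellipse_boundary)
    xs <- c(sc[, 1], unlist(lapply(bounds, function(b) b[, 1])))
    ys <- c(sc[, 2], unlist(lapply(bounds, function(b) b[, 2])))
    cols <- stats::setNames(
      grDevices::hcl.colors(max(2L, length(classes)), "Dark 3")[
        seq_along(classes)], classes)
    lab <- function(i) sprintf("CC%d (%.1f%%)", components[i],
                               100 * result$explained[components[i]])
    graphics::plot(range(xs), range(ys), type = "n",
                   xlab = lab(1), ylab = lab(2),
                   main = sprintf("ComDim scores, %.0f%% Hotelling ellipses",
                                  100 * confidence))
    graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
    for (cl in names(ellipses))
      graphics::lines(bounds[[cl]], col = cols[cl], lwd = 2)
    graphics::points(sc, pch = 19, col = cols[f])
    graphics::legend("topright", legend = classes, col = cols[classes],
                     pch = 19, bty = "n")
  }
  invisible(ellipses)
}

#' Serialize ellipse specs to JSON
#' @param ellipses named list of `ellipse_spec` (as from [score_plot()]).
#' @param path output JSON path.
#' @export
write_ellipses <- function(ellipses, path) {
  out <- lapply(ellipses, function(e)
    list(label = e$label, center = e$center, semi_axes = e$semi_axes,
         angle = e$angle, confidence = e$confidence, n = e$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
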