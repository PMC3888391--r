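# Barycentric <-> Cartesian mapping for the 2-simplex.
# Vertices: left = (0,0) maximal VI', right = (1,0) maximal dH',
# apex = (1/2, sqrt(3)/2) maximal 2MI'.
bary_to_cart <- function(dH_norm, mi2_norm, vi_norm) {
  cbind(x = dH_norm + mi2_norm / 2, y = mi2_norm * sqrt(3) / 2)
}

cart_to_bary <- function(x, y) {
  mi2 <- 2 * y / sqrt(3)
  dH <- x - mi2 / 2
  cbind(dH_norm = dH, mi2_norm = mi2, vi_norm = 1 - dH - mi2)
}

coords_frame <- function(points) {
  if (inherits(points, "triangle_coordinates")) points <- list(points)
  if (is.data.frame(points)) {
    df <- points
  } else if (is.list(points)) {
    df <- do.call(rbind, lapply(points, as.data.frame))
  } else {
    stop("points must be triangle_coordinates, a list of them, or a data frame")
  }
  need <- c("dH_norm", "mi2_norm", "vi_norm")
  if (!all(need %in% names(df))) {
    stop("coordinate columns dH_norm, mi2_norm, vi_norm are required")
  }
  off <- abs(df$dH_norm + df$mi2_norm + df$vi_norm - 1)
  if (any(off > 1e-6)) {
    stop(sprintf("coordinate triple off the simplex by %.2e", max(off)))
  }
  df
}

draw_triangle_frame <- function(annotate_zones = TRUE, main = "") {
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.12), ylim = c(-0.12, 1.02),
                        asp = 1)
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  graphics::lines(verts[, 1], verts[, 2])
  graphics::title(main = main)
  graphics::text(0.5, sqrt(3) / 2 + 0.05, "2MI' = 1", cex = 0.8)
  graphics::text(1.05, -0.05, "dH' = 1", cex = 0.8)
  graphics::text(-0.05, -0.05, "VI' = 1", cex = 0.8)
  if (annotate_zones) {
    graphics::text(0.5, sqrt(3) / 2 + 0.11, "best classifiers", cex = 0.7,
                   font = 3)
    graphics::text(1.05, -0.11, "specialized (majority)", cex = 0.7, font = 3)
    graphics::text(-0.05, -0.11, "worst (uninformative)", cex = 0.7, font = 3)
  }
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported figure format: .", ext,
              " (use .png, .svg or .pdf)"))
}

#' Plot points on the entropy triangle
#'
#' Renders barycentric coordinates \eqn{(\Delta H', 2MI', VI')} on the De
#' Finetti diagram. The apex carries maximal normalized mutual information
#' (the best classifiers), the right vertex maximal divergence from
#' uniformity (specialized/majority classifiers), the left vertex maximal
#' variation of information (the worst classifiers).
#'
#' @param points a `triangle_coordinates` object, a list of them, or a data
#'   frame with columns `dH_norm`, `mi2_norm`, `vi_norm` (e.g. an
#'   [accuracy_sweep()]).
#' @param color_by optional numeric vector (or, for a data frame, a column
#'   name such as `"accuracy"`, `"ema"`, `"nit"`, `"mi2_norm"`) mapped to a
#'   color scale with a side bar.
#' @param labels optional point labels.
#' @param annotate_zones draw the interpretive vertex annotations.
#' @param path optional output file (`.png`, `.svg` or `.pdf`); when `NULL`
#'   draws on the active device.
#' @param main plot title.
#' @param pch,cex base plotting parameters for the markers.
#' @param width,height device size in inches when `path` is given.
#' @return the Cartesian point matrix, invisibly; when `path` is given the
#'   file is written.
#' @examples
#' plot_triangle(triangle_coordinates(diag(2) * 10))
#' @export
plot_triangle <- function(points, color_by = NULL, labels = NULL,
                          annotate_zones = TRUE, path = NULL,
                          main = "Entropy triangle", pch = 19, cex = 0.9,
                          width = 6, height = 5.5) {
  df <- coords_frame(points)
  if (is.character(color_by) && length(color_by) == 1L) {
    if (!color_by %in% names(df)) stop("no column '", color_by, "' to color by")
    color_vals <- df[[color_by]]
    color_lab <- color_by
  } else {
    color_vals <- color_by
    color_lab <- deparse(substitute(color_by))
  }
  if (!is.null(color_vals) && any(!is.finite(color_vals))) {
    stop("color values must be finite")
  }
  if (!is.null(path)) {
    open_device(path, width, height)
    on.exit(grDevices::dev.off())
  }
  draw_triangle_frame(annotate_zones = annotate_zones, main = main)
  xy <- bary_to_cart(df$dH_norm, df$mi2_norm, df$vi_norm)
  if (is.null(color_vals)) {
    cols <- "steelblue"
  } else {
    pal <- grDevices::hcl.colors(100, "viridis")
    rng <- range(color_vals)
    idx <- if (diff(rng) == 0) rep(50L, length(color_vals)) else {
      1L + as.integer(99 * (color_vals - rng[1]) / diff(rng))
    }
    cols <- pal[idx]
    # side color bar
    ybar <- seq(0.15, 0.75, length.out = 101)
    graphics::rect(1.08, ybar[-101], 1.11, ybar[-1], col = pal, border = NA)
    graphics::text(1.095, 0.79, color_lab, cex = 0.7)
    graphics::text(1.13, 0.15, formatC(rng[1], digits = 2, format = "g"),
                   cex = 0.6, adj = 0)
    graphics::text(1.13, 0.75, formatC(rng[2], digits = 2, format = "g"),
                   cex = 0.6, adj = 0)
  }
  graphics::points(xy[, 1], xy[, 2], pch = pch, cex = cex, col = cols)
  if (!is.null(labels)) {
    graphics::text(xy[, 1], xy[, 2], labels, pos = 3, cex = 0.7)
  }
  invisible(xy)
}

#' @export
plot.triangle_coordinates <- function(x, ...) plot_triangle(x, ...)

#' @export
plot.accuracy_sweep <- function(x, color_by = "accuracy", ...) {
  plot_triangle(x, color_by = color_by, ...)
}

#' Plot the split entropy triangle
#'
#' Draws the per-variable balance coordinates of each classifier — the
#' input (X) point and the output (Y) point — joined by a tie line on one
#' triangle. A perfect classifier has both points at the apex; a
#' constant-output (majority) classifier puts the X point at the
#' variation-of-information vertex and the Y point at the divergence
#' vertex.
#'
#' @param points_X,points_Y split coordinates per classifier, as returned in
#'   the `X` and `Y` elements of [split_coordinates()]: single objects,
#'   lists, or data frames. Must be paired (equal length).
#' @inheritParams plot_triangle
#' @return invisibly, a list of the two Cartesian point matrices.
#' @export
plot_split_triangle <- function(points_X, points_Y, labels = NULL,
                                annotate_zones = TRUE, path = NULL,
                                main = "Split entropy triangle",
                                width = 6, height = 5.5) {
  dx <- coords_frame(points_X)
  dy <- coords_frame(points_Y)
  if (nrow(dx) != nrow(dy)) {
    stop("unpaired split coordinates: ", nrow(dx), " X points vs ",
         nrow(dy), " Y points")
  }
  if (!is.null(path)) {
    open_device(path, width, height)
    on.exit(grDevices::dev.off())
  }
  draw_triangle_frame(annotate_zones = annotate_zones, main = main)
  cx <- bary_to_cart(dx$dH_norm, dx$mi2_norm, dx$vi_norm)
  cy <- bary_to_cart(dy$dH_norm, dy$mi2_norm, dy$vi_norm)
  graphics::segments(cx[, 1], cx[, 2], cy[, 1], cy[, 2], col = "grey60")
  graphics::points(cx[, 1], cx[, 2], pch = 17, col = "firebrick")
  graphics::points(cy[, 1], cy[, 2], pch = 19, col = "navy")
  graphics::legend("topleft", legend = c("X (true)", "Y (predicted)"),
                   pch = c(17, 19), col = c("firebrick", "navy"),
                   bty = "n", cex = 0.8)
  if (!is.null(labels)) {
    graphics::text(cx[, 1], cx[, 2], labels, pos = 3, cex = 0.7)
  }
  invisible(list(X = cx, Y = cy))
}
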