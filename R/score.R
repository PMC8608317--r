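# Edge matching and Hazard Visibility Score. Every ground-truth geometry
# pixel is scored by how close (in pixels) the nearest detected luminance
# boundary lies; the score falls from 1 at zero separation to 0 at a
# falloff distance expressed in visual angle, and the HVS of a region of
# interest is the mean score over the geometry pixels inside it.

#' Nearest-boundary distance for every geometry pixel
#'
#' Exact Euclidean distance (pixels) from each geometry-edge pixel to the
#' nearest luminance-boundary pixel, via [distance_transform()]. An empty
#' boundary map yields `Inf` for every geometry pixel.
#'
#' @param geometry An [edge_map()] of ground-truth geometric edges.
#' @param boundaries An [edge_map()] of detected luminance boundaries,
#'   same shape.
#' @return An object of class `visibility_distances`: data.frame with
#'   columns `row`, `col`, `distance` (one row per geometry pixel), with
#'   the grid shape and `ppd`-free metadata attached.
#' @export
nearest_boundary_distances <- function(geometry, boundaries) {
  stopifnot(inherits(geometry, "edge_map"), inherits(boundaries, "edge_map"))
  if (!identical(dim(geometry$mask), dim(boundaries$mask)))
    stop("geometry and boundary maps must have the same shape", call. = FALSE)
  idx <- which(geometry$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    d <- numeric(0)
  } else if (!any(boundaries$mask)) {
    d <- rep(Inf, nrow(idx))
  } else {
    dt <- distance_transform(boundaries$mask)
    d <- dt[idx]
  }
  structure(data.frame(row = idx[, 1], col = idx[, 2], distance = d),
            shape = dim(geometry$mask), class = c("visibility_distances",
                                                  "data.frame"))
}

#' Map a pixel separation to a 0--1 visibility score
#'
#' Default linear falloff `max(0, 1 - d / d_max)`, with the falloff
#' distance `d_max` given in degrees of visual angle and converted to
#' pixels through `ppd`, so scores do not depend on image resolution.
#' Infinite separations (no boundary anywhere) score 0. An exponential
#' kernel `exp(-d / d_max_px)` is available as an alternative monotone
#' mapping.
#'
#' @param d Distances in pixels (vectorised; `Inf` allowed).
#' @param ppd Pixels per degree of the source image.
#' @param d_max_deg Falloff extent in degrees of visual angle
#'   (default 0.5).
#' @param kernel `"linear"` (default) or `"exponential"`.
#' @return Scores in `[0, 1]`, non-increasing in `d`.
#' @export
score_from_distance <- function(d, ppd, d_max_deg = 0.5,
                                kernel = c("linear", "exponential")) {
  kernel <- match.arg(kernel)
  if (!is.finite(d_max_deg) || d_max_deg <= 0)
    stop("`d_max_deg` must be positive", call. = FALSE)
  if (!is.finite(ppd) || ppd <= 0)
    stop("`ppd` must be positive", call. = FALSE)
  if (any(d < 0, na.rm = TRUE)) stop("distances must be >= 0", call. = FALSE)
  d_max_px <- d_max_deg * ppd
  s <- switch(kernel,
              linear = pmax(0, 1 - d / d_max_px),
              exponential = exp(-d / d_max_px))
  s[!is.finite(d)] <- 0
  s
}

#' Hazard Visibility Score over a region of interest
#'
#' Mean of the per-pixel visibility scores across the geometry pixels that
#' fall inside the ROI. An ROI containing no geometry pixels is an error
#' (never a silent zero).
#'
#' @param distances A [nearest_boundary_distances()] result.
#' @param roi Logical ROI mask (same grid), or `NULL` for all geometry
#'   pixels.
#' @param ppd Pixels per degree of the source image.
#' @inheritParams score_from_distance
#' @return The scalar HVS in `[0, 1]`.
#' @export
hazard_visibility_score <- function(distances, roi = NULL, ppd,
                                    d_max_deg = 0.5,
                                    kernel = c("linear", "exponential")) {
  stopifnot(inherits(distances, "visibility_distances"))
  shape <- attr(distances, "shape")
  if (is.null(roi)) {
    inside <- rep(TRUE, nrow(distances))
  } else {
    if (!is.matrix(roi) || !identical(dim(roi), as.integer(shape)) &&
        !identical(dim(roi), shape))
      stop("`roi` must be a mask matching the image grid", call. = FALSE)
    inside <- roi[cbind(distances$row, distances$col)] > 0
  }
  if (!any(inside))
    stop("ROI contains no geometry pixels: HVS is undefined for an empty ROI",
         call. = FALSE)
  s <- score_from_distance(distances$distance[inside], ppd = ppd,
                           d_max_deg = d_max_deg, kernel = kernel)
  mean(s)
}

#' Red-green visibility overlay
#'
#' Renders the scored geometry pixels on a red (score 0, poor match) to
#' green (score 1, good match) ramp over the grayscale luminance image.
#'
#' @param img The underlying [luminance_image()] (or matrix).
#' @param distances A [nearest_boundary_distances()] result for the scene.
#' @param ppd Pixels per degree (defaults to the image's own).
#' @inheritParams score_from_distance
#' @param dilate Half-width in pixels by which scored pixels are thickened
#'   for display (default 1).
#' @return An `nrow x ncol x 3` array in `[0, 1]` (RGB).
#' @export
render_visibility_overlay <- function(img, distances, ppd = NULL,
                                      d_max_deg = 0.5,
                                      kernel = c("linear", "exponential"),
                                      dilate = 1L) {
  m <- if (inherits(img, "luminance_image")) img$values else img
  if (is.null(ppd)) {
    if (!inherits(img, "luminance_image"))
      stop("`ppd` required when `img` is a plain matrix", call. = FALSE)
    ppd <- img$ppd
  }
  stopifnot(inherits(distances, "visibility_distances"))
  g <- m / max(m, 1e-12)
  out <- array(rep(g, 3L), dim = c(nrow(m), ncol(m), 3L))
  s <- score_from_distance(distances$distance, ppd = ppd,
                           d_max_deg = d_max_deg, kernel = kernel)
  for (k in seq_len(nrow(distances))) {
    rr <- distances$row[k] + (-dilate:dilate)
    cc <- distances$col[k] + (-dilate:dilate)
    rr <- rr[rr >= 1 & rr <= nrow(m)]
    cc <- cc[cc >= 1 & cc <= ncol(m)]
    out[rr, cc, 1] <- 1 - s[k]
    out[rr, cc, 2] <- s[k]
    out[rr, cc, 3] <- 0
  }
  out
}
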