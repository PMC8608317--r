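# Synthetic walkway/step stimulus family: a desk-scale stand-in for
# photometric global-illumination renders. A pinhole camera views a
# 30-ft walkway, 4-ft wide, with one of five step targets at 10 ft;
# surfaces are Lambertian under one of five point-light arrangements and
# the camera takes one of five viewpoints. Alongside the luminance image
# the renderer emits the ground-truth geometric-edge mask (projected depth
# and orientation discontinuities, with occlusion handling) and region-of-
# interest masks around the target.

#' @export
scene_targets <- function() c("flat", "big-step-up", "big-step-down",
                              "small-step-up", "small-step-down")
#' @export
scene_lightings <- function() c("overhead", "far-panel", "near-panel",
                                "spotlight-1", "spotlight-2")
#' @export
scene_viewpoints <- function() c("center", "pivot-left", "pivot-right",
                                 "rotate-down", "rotate-up")

#' Specify a walkway/step scene
#'
#' @param target One of `scene_targets()`: a flat walkway or a 7-inch
#'   ("big") or 1-inch ("small") step up or down at the target distance.
#' @param lighting One of `scene_lightings()` (point-light arrangements).
#' @param viewpoint One of `scene_viewpoints()`: the center gaze or a yaw
#'   pivot / pitch rotation about it.
#' @param walkway_length,walkway_width Walkway dimensions in feet
#'   (defaults 30 and 4).
#' @param big_step_in,small_step_in Step riser heights in inches
#'   (defaults 7 and 1).
#' @param target_distance Distance from the eye to the step, feet
#'   (default 10).
#' @param eye_height Eye height above the near floor, feet (default 5).
#' @param image_size Image height and width in pixels (default 512).
#' @param ppd Pixels per degree of visual angle at the image centre
#'   (default 20).
#' @param pivot_deg,rotate_deg Yaw and pitch offsets (degrees) applied for
#'   the pivot-* and rotate-* viewpoints (default 6).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(target = "flat", lighting = "overhead",
                       viewpoint = "center",
                       walkway_length = 30, walkway_width = 4,
                       big_step_in = 7, small_step_in = 1,
                       target_distance = 10, eye_height = 5,
                       image_size = c(512, 512), ppd = 20,
                       pivot_deg = 6, rotate_deg = 6) {
  target <- match.arg(target, scene_targets())
  lighting <- match.arg(lighting, scene_lightings())
  viewpoint <- match.arg(viewpoint, scene_viewpoints())
  image_size <- rep(as.integer(image_size), length.out = 2L)
  dims <- c(walkway_length, walkway_width, big_step_in, small_step_in,
            target_distance, eye_height, ppd, image_size)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all scene dimensions must be positive and finite", call. = FALSE)
  structure(list(target = target, lighting = lighting, viewpoint = viewpoint,
                 walkway_length = walkway_length,
                 walkway_width = walkway_width,
                 big_step_in = big_step_in, small_step_in = small_step_in,
                 target_distance = target_distance, eye_height = eye_height,
                 image_size = image_size, ppd = ppd,
                 pivot_deg = pivot_deg, rotate_deg = rotate_deg),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene: %s | %s | %s (%dx%d px, %.1f ppd)\n", x$target,
              x$lighting, x$viewpoint, x$image_size[1], x$image_size[2],
              x$ppd))
  invisible(x)
}

step_height_ft <- function(spec) {
  switch(spec$target,
         "flat" = 0,
         "big-step-up" = spec$big_step_in / 12,
         "big-step-down" = -spec$big_step_in / 12,
         "small-step-up" = spec$small_step_in / 12,
         "small-step-down" = -spec$small_step_in / 12)
}

#' Visual angle subtended by a frontal extent
#'
#' Full subtended angle `2 * atan(extent / (2 * distance))` in degrees.
#' A 7-inch riser at 10 ft subtends about 3.3 degrees; the 4-ft step width
#' at 10 ft about 23 degrees.
#'
#' @param extent Frontal extent (any length unit, `>= 0`).
#' @param distance Viewing distance in the same unit (`> 0`).
#' @return Angle in degrees (vectorised).
#' @examples
#' visual_angle(7, 120)   # inches: ~3.34 degrees
#' visual_angle(48, 120)  # ~22.6 degrees
#' @export
visual_angle <- function(extent, distance) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("`distance` must be positive and finite", call. = FALSE)
  if (any(!is.finite(extent)) || any(extent < 0))
    stop("`extent` must be non-negative and finite", call. = FALSE)
  2 * atan(extent / (2 * distance)) * 180 / pi
}

# --- camera ------------------------------------------------------------------

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a),
                              0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)

# Camera pose: eye position, rotation (columns = right, up, forward in
# world coordinates), focal length in pixels.
scene_camera <- function(spec) {
  eye <- c(0, spec$eye_height, 0)
  pitch0 <- -atan2(spec$eye_height, spec$target_distance)
  yaw <- 0; pitch <- pitch0
  d <- pi / 180
  switch(spec$viewpoint,
         "center" = NULL,
         "pivot-left"  = { yaw <- spec$pivot_deg * d },
         "pivot-right" = { yaw <- -spec$pivot_deg * d },
         "rotate-down" = { pitch <- pitch0 - spec$rotate_deg * d },
         "rotate-up"   = { pitch <- pitch0 + spec$rotate_deg * d })
  R <- rot_y(yaw) %*% rot_x(pitch)
  list(eye = eye, R = R, f_px = spec$ppd * 180 / pi,
       nr = spec$image_size[1], nc = spec$image_size[2])
}

# World-space unit ray directions for every pixel: three nr x nc matrices.
camera_rays <- function(cam) {
  nr <- cam$nr; nc <- cam$nc
  u <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
  v <- matrix((nr + 1) / 2 - seq_len(nr), nr, nc)
  f <- matrix(cam$f_px, nr, nc)
  n <- sqrt(u^2 + v^2 + f^2)
  dx_c <- u / n; dy_c <- v / n; dz_c <- f / n
  R <- cam$R
  list(x = R[1, 1] * dx_c + R[1, 2] * dy_c + R[1, 3] * dz_c,
       y = R[2, 1] * dx_c + R[2, 2] * dy_c + R[2, 3] * dz_c,
       z = R[3, 1] * dx_c + R[3, 2] * dy_c + R[3, 3] * dz_c)
}

# Project world points (n x 3) to pixel (row, col); z_cam <= 0 -> NA.
project_points <- function(cam, p) {
  rel <- sweep(p, 2, cam$eye)
  pc <- rel %*% cam$R   # camera coordinates (right, up, forward)
  ok <- pc[, 3] > 1e-9
  row <- col <- rep(NA_real_, nrow(p))
  col[ok] <- cam$f_px * pc[ok, 1] / pc[ok, 3] + (cam$nc + 1) / 2
  row[ok] <- (cam$nr + 1) / 2 - cam$f_px * pc[ok, 2] / pc[ok, 3]
  cbind(row = row, col = col, dist = sqrt(rowSums(rel^2)))
}

# --- geometry ----------------------------------------------------------------

# Surfaces: axis-aligned rectangles. Each is a list(axis, level, lim1, lim2,
# normal, rho) where axis "y" means plane y = level bounded in x (lim1) and
# z (lim2); axis "z" bounded in x, y; axis "x" bounded in y, z.
scene_surfaces <- function(spec) {
  w <- spec$walkway_width / 2
  zs <- spec$target_distance
  L <- spec$walkway_length
  h <- step_height_ft(spec)
  xmax <- 10
  rho_walk <- 0.5
  rho_side <- 0.22
  surf <- list(
    list(axis = "y", level = 0, xlim = c(-w, w), zlim = c(0, zs),
         normal = c(0, 1, 0), rho = rho_walk),
    list(axis = "y", level = 0, xlim = c(-xmax, -w), zlim = c(0, L),
         normal = c(0, 1, 0), rho = rho_side),
    list(axis = "y", level = 0, xlim = c(w, xmax), zlim = c(0, L),
         normal = c(0, 1, 0), rho = rho_side),
    list(axis = "y", level = h, xlim = c(-w, w), zlim = c(zs, L),
         normal = c(0, 1, 0), rho = rho_walk)
  )
  if (h > 0) {
    surf <- c(surf, list(
      list(axis = "z", level = zs, xlim = c(-w, w), ylim = c(0, h),
           normal = c(0, 0, -1), rho = rho_walk)))
  } else if (h < 0) {
    # inner walls of the dropped section, visible near the corners
    surf <- c(surf, list(
      list(axis = "x", level = -w, ylim = c(h, 0), zlim = c(zs, L),
           normal = c(1, 0, 0), rho = rho_walk),
      list(axis = "x", level = w, ylim = c(h, 0), zlim = c(zs, L),
           normal = c(-1, 0, 0), rho = rho_walk)))
  }
  surf
}

scene_lights <- function(spec) {
  zs <- spec$target_distance
  cfg <- switch(spec$lighting,
    "overhead"    = list(pos = c(0, 9, zs), intensity = 5000),
    "far-panel"   = list(pos = c(0, 8, zs + 12), intensity = 6000),
    "near-panel"  = list(pos = c(0, 8, 3), intensity = 6000),
    "spotlight-1" = list(pos = c(-5, 7, zs - 4), intensity = 4500),
    "spotlight-2" = list(pos = c(4, 6, zs + 6), intensity = 4000))
  c(cfg, list(ambient = 40))
}

# Intersect rays (lists of x/y/z direction arrays, shared origin) with the
# surface set; returns hit distance, surface index, hit coordinates.
intersect_scene <- function(origin, rays, surfaces) {
  shp <- dim(rays$x)
  if (is.null(shp)) shp <- length(rays$x)
  t_best <- array(Inf, dim = shp)
  idx <- array(0L, dim = shp)
  for (s in seq_along(surfaces)) {
    sf <- surfaces[[s]]
    dn <- switch(sf$axis, x = rays$x, y = rays$y, z = rays$z)
    on <- switch(sf$axis, x = origin[1], y = origin[2], z = origin[3])
    nd <- sum(sf$normal * c(
      switch(sf$axis, x = 1, 0), switch(sf$axis, y = 1, 0),
      switch(sf$axis, z = 1, 0)))
    t <- (sf$level - on) / dn
    px <- origin[1] + t * rays$x
    py <- origin[2] + t * rays$y
    pz <- origin[3] + t * rays$z
    ok <- is.finite(t) & t > 1e-6 & (dn * nd < 0)  # front-facing only
    if (!is.null(sf$xlim)) ok <- ok & px >= sf$xlim[1] & px <= sf$xlim[2]
    if (!is.null(sf$ylim)) ok <- ok & py >= sf$ylim[1] & py <= sf$ylim[2]
    if (!is.null(sf$zlim)) ok <- ok & pz >= sf$zlim[1] & pz <= sf$zlim[2]
    win <- ok & t < t_best
    t_best[win] <- t[win]
    idx[win] <- s
  }
  list(t = t_best, surface = idx)
}

# Lambertian direct shading (no cast shadows): L = rho * (E_light + E_amb) / pi
shade_scene <- function(origin, rays, surfaces, light) {
  hit <- intersect_scene(origin, rays, surfaces)
  lum <- array(0, dim = dim(hit$t))
  for (s in seq_along(surfaces)) {
    sel <- hit$surface == s
    if (!any(sel)) next
    sf <- surfaces[[s]]
    t <- hit$t[sel]
    px <- origin[1] + t * rays$x[sel]
    py <- origin[2] + t * rays$y[sel]
    pz <- origin[3] + t * rays$z[sel]
    lx <- light$pos[1] - px; ly <- light$pos[2] - py; lz <- light$pos[3] - pz
    r2 <- lx^2 + ly^2 + lz^2
    r <- sqrt(r2)
    ndotl <- (sf$normal[1] * lx + sf$normal[2] * ly + sf$normal[3] * lz) / r
    E <- light$intensity * pmax(0, ndotl) / r2
    lum[sel] <- sf$rho * (E + light$ambient) / pi
  }
  lum
}

# Geometric discontinuity curves as 3-D segments (list of 2x3 matrices).
scene_geometry_segments <- function(spec) {
  w <- spec$walkway_width / 2
  zs <- spec$target_distance
  L <- spec$walkway_length
  h <- step_height_ft(spec)
  seg <- function(a, b) rbind(a, b)
  segs <- list(
    seg(c(-w, 0, 0), c(-w, 0, zs)),   # near walkway borders
    seg(c(w, 0, 0), c(w, 0, zs))
  )
  if (h == 0) {
    segs <- c(segs, list(
      seg(c(-w, 0, zs), c(-w, 0, L)),
      seg(c(w, 0, zs), c(w, 0, L))))
  } else {
    y_top <- max(h, 0); y_bot <- min(h, 0)
    segs <- c(segs, list(
      seg(c(-w, y_top, zs), c(w, y_top, zs)),  # riser top edge
      seg(c(-w, y_bot, zs), c(w, y_bot, zs)),  # riser bottom edge
      seg(c(-w, y_bot, zs), c(-w, y_top, zs)), # corner verticals
      seg(c(w, y_bot, zs), c(w, y_top, zs)),
      seg(c(-w, h, zs), c(-w, h, L)),          # far walkway borders
      seg(c(w, h, zs), c(w, h, L))))
  }
  segs
}

# Rasterise 3-D segments to a 1-px mask, dropping occluded sample points.
rasterize_segments <- function(cam, segs, surfaces) {
  mask <- matrix(FALSE, cam$nr, cam$nc)
  n_off <- 0L
  for (sg in segs) {
    pr <- project_points(cam, sg)
    if (all(is.na(pr[, "row"]))) next
    px_len <- sqrt(diff(pr[, "row"])^2 + diff(pr[, "col"])^2)
    if (!is.finite(px_len)) px_len <- max(cam$nr, cam$nc)
    n <- max(8L, ceiling(3 * px_len))
    tt <- seq(0, 1, length.out = n)
    pts <- cbind(sg[1, 1] + tt * (sg[2, 1] - sg[1, 1]),
                 sg[1, 2] + tt * (sg[2, 2] - sg[1, 2]),
                 sg[1, 3] + tt * (sg[2, 3] - sg[1, 3]))
    pp <- project_points(cam, pts)
    ok <- is.finite(pp[, "row"]) & is.finite(pp[, "col"])
    # occlusion: the point must be the first scene hit along its sight line
    rel <- sweep(pts, 2, cam$eye)
    dist <- pp[, "dist"]
    dirs <- list(x = rel[, 1] / dist, y = rel[, 2] / dist, z = rel[, 3] / dist)
    hit <- intersect_scene(cam$eye, dirs, surfaces)
    ok <- ok & (hit$t >= dist - 1e-4)
    ri <- round(pp[ok, "row"]); ci <- round(pp[ok, "col"])
    inb <- ri >= 1 & ri <= cam$nr & ci >= 1 & ci <= cam$nc
    n_off <- n_off + sum(!inb)
    mask[cbind(ri[inb], ci[inb])] <- TRUE
  }
  attr(mask, "n_outside") <- n_off
  mask
}

# Pixels whose rays pass through an axis-aligned box (slab test).
ray_box_mask <- function(origin, rays, box) {
  slab <- function(o, d, lim) {
    d <- ifelse(abs(d) < 1e-12, 1e-12, d)  # avoid 0/0 for axis-parallel rays
    t1 <- (lim[1] - o) / d
    t2 <- (lim[2] - o) / d
    list(lo = pmin(t1, t2), hi = pmax(t1, t2))
  }
  sx <- slab(origin[1], rays$x, box$x)
  sy <- slab(origin[2], rays$y, box$y)
  sz <- slab(origin[3], rays$z, box$z)
  t_in <- pmax(sx$lo, sy$lo, sz$lo)
  t_out <- pmin(sx$hi, sy$hi, sz$hi)
  t_in <= t_out & t_out > 0
}

# Named ROI masks around the step footprint. Corners take the outer
# `corner_frac` of the step width each side; the central edge the rest.
scene_roi_masks <- function(spec, cam, rays, corner_frac = 0.15) {
  w <- spec$walkway_width / 2
  zs <- spec$target_distance
  h <- step_height_ft(spec)
  ylo <- min(h, 0) - 0.15; yhi <- max(h, 0) + 0.15
  zlim <- c(zs - 0.5, zs + 0.5)
  cw <- corner_frac * spec$walkway_width
  box <- function(xlim) list(x = xlim, y = c(ylo, yhi), z = zlim)
  whole <- ray_box_mask(cam$eye, rays, box(c(-w - 0.25, w + 0.25)))
  left <- ray_box_mask(cam$eye, rays, box(c(-w - 0.25, -w + cw)))
  right <- ray_box_mask(cam$eye, rays, box(c(w - cw, w + 0.25)))
  central <- ray_box_mask(cam$eye, rays, box(c(-w + cw, w - cw)))
  list("whole-step" = whole, "corners" = left | right,
       "central-edge" = central)
}

#' Render a walkway/step scene
#'
#' Pinhole projection of the 3-D walkway model with direct Lambertian
#' shading under the scene's point light (no global illumination and no
#' cast shadows; the synthetic family reproduces the structural contrast
#' patterns of the stimulus set, not absolute photometry). Also produces
#' the ground-truth geometric-edge mask (projected depth/orientation
#' discontinuities, occlusion-tested, 1 px wide) and the named ROI masks
#' `whole-step`, `corners` and `central-edge`.
#'
#' @param spec A [scene_spec()].
#' @param supersample Integer antialiasing factor: shading is evaluated on
#'   an `supersample`-times finer ray grid and box-averaged down. This
#'   encodes the sub-pixel position of each surface boundary in the pixel
#'   intensities, so detected luminance boundaries land on the same pixel
#'   that the geometric edge rasterises to instead of being committed to an
#'   arbitrary side of the transition. `1` disables antialiasing.
#' @return An object of class `scene_render`: fields `luminance`
#'   ([luminance_image()]), `geometry_edges` ([edge_map()], source
#'   `"geometry"`), `rois` (named list of logical masks) and `spec`.
#' @export
render_scene <- function(spec, supersample = 2L) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- as.integer(supersample)
  if (is.na(s) || s < 1L) stop("`supersample` must be a positive integer",
                               call. = FALSE)
  cam <- scene_camera(spec)
  # the target must be in the field of view
  tgt <- matrix(c(0, step_height_ft(spec) / 2, spec$target_distance), 1)
  pj <- project_points(cam, tgt)
  if (is.na(pj[1, "row"]) || pj[1, "row"] < 1 || pj[1, "row"] > cam$nr ||
      pj[1, "col"] < 1 || pj[1, "col"] > cam$nc)
    stop("target lies outside the field of view for this camera configuration",
         call. = FALSE)
  rays <- camera_rays(cam)
  surfaces <- scene_surfaces(spec)
  light <- scene_lights(spec)
  if (s == 1L) {
    lum <- shade_scene(cam$eye, rays, surfaces, light)
  } else {
    # shade on a finer grid with a proportionally longer focal length
    # (sub-pixel centroids then tile each final pixel exactly), and
    # box-average back down
    cam_s <- cam
    cam_s$nr <- cam$nr * s; cam_s$nc <- cam$nc * s; cam_s$f_px <- cam$f_px * s
    lum_s <- shade_scene(cam$eye, camera_rays(cam_s), surfaces, light)
    ri <- rep(seq_len(cam$nr), each = s)
    ci <- rep(seq_len(cam$nc), each = s)
    lum <- t(rowsum(t(rowsum(lum_s, ri)), ci)) / s^2
  }
  geom <- rasterize_segments(cam, scene_geometry_segments(spec), surfaces)
  n_off <- attr(geom, "n_outside")
  rois <- scene_roi_masks(spec, cam, rays)
  structure(list(
    luminance = luminance_image(lum, ppd = spec$ppd, provenance = "synthetic"),
    geometry_edges = edge_map(geom, "geometry",
                              params = list(n_outside_image = n_off)),
    rois = rois,
    spec = spec
  ), class = "scene_render")
}

#' @export
print.scene_render <- function(x, ...) {
  print(x$spec)
  print(x$luminance)
  print(x$geometry_edges)
  cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the factorial trial design
#'
#' Full crossing of targets, lightings, viewpoints and repetitions in a
#' deterministic order (randomise at presentation time with an explicit
#' seed, not here). The default design has 5 x 5 x 5 x 2 = 250 trials.
#'
#' @param n_targets,n_lighting,n_viewpoints Number of levels used from each
#'   factor enumeration (1--5).
#' @param n_reps Repetitions of each cell.
#' @return A data.frame with columns `trial`, `target`, `lighting`,
#'   `viewpoint`, `repetition`.
#' @export
enumerate_design <- function(n_targets = 5, n_lighting = 5,
                             n_viewpoints = 5, n_reps = 2) {
  counts <- c(n_targets, n_lighting, n_viewpoints, n_reps)
  if (any(counts < 1) || any(counts[1:3] > 5))
    stop("factor counts must be >= 1 (and <= 5 for the scene factors)",
         call. = FALSE)
  g <- expand.grid(
    repetition = seq_len(n_reps),
    viewpoint = scene_viewpoints()[seq_len(n_viewpoints)],
    lighting = scene_lightings()[seq_len(n_lighting)],
    target = scene_targets()[seq_len(n_targets)],
    stringsAsFactors = FALSE)
  g <- g[, c("target", "lighting", "viewpoint", "repetition")]
  data.frame(trial = seq_len(nrow(g)), g, row.names = NULL)
}

#' Export a rendered scene to files
#'
#' Writes the luminance image (PFM plus YAML sidecar), the geometry-edge
#' and ROI masks (PNG) and the scene specification (YAML).
#'
#' @param render A [render_scene()] result.
#' @param dir Output directory (created if needed).
#' @param basename File name stem.
#' @return The directory, invisibly.
#' @export
write_scene_render <- function(render, dir, basename = "scene") {
  stopifnot(inherits(render, "scene_render"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_luminance_image(render$luminance,
                        file.path(dir, paste0(basename, ".pfm")))
  write_edge_map(render$geometry_edges,
                 file.path(dir, paste0(basename, "_geometry.png")))
  for (nm in names(render$rois)) {
    png::writePNG(render$rois[[nm]] * 1,
                  file.path(dir, paste0(basename, "_roi_", nm, ".png")))
  }
  yaml::write_yaml(unclass(render$spec),
                   file.path(dir, paste0(basename, ".yaml")))
  invisible(dir)
}
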