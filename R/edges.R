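# Luminance-boundary extraction (Canny) and exact Euclidean distance
# transforms for edge matching.

#' Binary edge map
#'
#' @param mask Logical or 0/1 matrix.
#' @param source `"luminance"` (detected boundaries) or `"geometry"`
#'   (ground-truth geometric edges).
#' @param params Optional named list recording extraction parameters.
#' @return An object of class `edge_map` (strictly binary logical matrix
#'   plus metadata).
#' @export
edge_map <- function(mask, source = c("luminance", "geometry"),
                     params = list()) {
  source <- match.arg(source)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("numeric edge masks must contain only 0 and 1", call. = FALSE)
    mask <- mask > 0
  }
  if (!is.logical(mask)) stop("`mask` must be logical or 0/1", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, source = source, params = params),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("Edge map (%s): %d x %d px, %d edge pixels\n", x$source,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' @export
dim.edge_map <- function(x) dim(x$mask)

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# separable Gaussian smoothing with reflected borders
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  p <- mirror_pad(m, half, half)
  x <- p$m
  # convolve columns then rows
  x <- apply(x, 2, function(col) stats::filter(col, k, sides = 2))
  x <- t(apply(x, 1, function(row) stats::filter(row, k, sides = 2)))
  crop_pad(x, half, half, nrow(m), ncol(m))
}

#' Detect luminance boundaries with the Canny operator
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and hysteresis linking. The operator runs
#' on log-luminance, so the gradient measures local Weber contrast per
#' pixel and the thresholds are absolute contrast steps: the output is
#' invariant to rescaling all luminances by a positive constant, and -
#' unlike thresholds tied to the image's maximum gradient - detection of a
#' given boundary does not depend on how sharp unrelated content elsewhere
#' in the image happens to be. Weak edge pixels survive only when
#' connected (8-neighbour) to a strong pixel.
#'
#' @param img A [luminance_image()] (or plain matrix).
#' @param sigma Gaussian smoothing scale in pixels (default 1).
#' @param low,high Hysteresis thresholds on the log-luminance gradient
#'   magnitude (dimensionless contrast per pixel); `0 < low < high`. The
#'   defaults accept boundaries whose smoothed luminance ratio changes by
#'   roughly ten percent per pixel.
#' @return An [edge_map()] with `source = "luminance"`. A constant image
#'   yields an empty map.
#' @export
detect_luminance_boundaries <- function(img, sigma = 1.0, low = 0.02,
                                        high = 0.05) {
  m <- if (inherits(img, "luminance_image")) img$values else img
  if (!(low > 0 && low < high))
    stop("need 0 < low < high", call. = FALSE)
  params <- list(sigma = sigma, low = low, high = high)
  mx <- max(m)
  if (mx <= 0 || diff(range(m)) == 0)
    return(edge_map(matrix(FALSE, nrow(m), ncol(m)), "luminance", params))
  # log-luminance with a floor at 1e-6 of the maximum so that zero
  # (unlit) pixels do not produce unbounded gradients
  m <- log(pmax(m / mx, 1e-6))
  s <- gaussian_blur(m, sigma)

  # Sobel gradients (row index increases downward); mirror padding so the
  # image border itself never registers as a luminance boundary
  nr <- nrow(s); nc <- ncol(s)
  p <- mirror_pad(s, 1, 1)$m
  shp <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (shp(0, -1) - shp(0, 1)) +
    0.5 * (shp(-1, -1) - shp(-1, 1)) +
    0.5 * (shp(1, -1) - shp(1, 1))
  gy <- (shp(-1, 0) - shp(1, 0)) +
    0.5 * (shp(-1, -1) - shp(1, -1)) +
    0.5 * (shp(-1, 1) - shp(1, 1))
  g <- sqrt(gx^2 + gy^2)
  if (max(g) == 0)
    return(edge_map(matrix(FALSE, nrow(m), ncol(m)), "luminance", params))

  # non-maximum suppression: compare with the two neighbours along the
  # gradient direction, quantised to 4 orientations
  ang <- atan2(gy, gx)  # [-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nb <- list(
    `0` = list(c(0, 1), c(0, -1)),
    `1` = list(c(-1, 1), c(1, -1)),
    `2` = list(c(-1, 0), c(1, 0)),
    `3` = list(c(-1, -1), c(1, 1))
  )
  keep <- matrix(FALSE, nrow(g), ncol(g))
  for (sct in 0:3) {
    d <- nb[[as.character(sct)]]
    n1 <- shift_mat(g, d[[1]][1], d[[1]][2])
    n2 <- shift_mat(g, d[[2]][1], d[[2]][2])
    keep <- keep | (sector == sct & g >= n1 & g >= n2)
  }
  strong <- keep & g >= high
  weak <- keep & g >= low

  # hysteresis: grow strong set through weak pixels (8-connected)
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | (weak & shift_mat(strong, dr, dc, fill = FALSE) > 0)
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  edge_map(strong, "luminance", params)
}

#' Write an edge map as a 1-bit PNG plus a JSON parameter record
#'
#' @param em An [edge_map()].
#' @param path Output PNG path; the parameter record is written beside it
#'   as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_edge_map <- function(em, path) {
  stopifnot(inherits(em, "edge_map"))
  png::writePNG(em$mask * 1, path)
  rec <- c(list(source = em$source,
                shape = dim(em$mask),
                n_edge_pixels = sum(em$mask)),
           em$params)
  writeLines(to_json(rec), paste0(path, ".json"))
  invisible(path)
}

# minimal JSON serialiser for flat parameter records (keeps jsonlite out
# of the package's hard dependencies)
to_json <- function(x) {
  enc <- function(v) {
    if (is.character(v)) paste0('"', v, '"') else format(v, digits = 12)
  }
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (length(v) == 1L) enc(v) else
      paste0("[", paste(vapply(v, enc, ""), collapse = ","), "]")
    paste0('"', nm, '":', val)
  }, "")
  paste0("{", paste(items, collapse = ","), "}")
}

#' Exact Euclidean distance transform of a binary mask
#'
#' Distance from every pixel to the nearest `TRUE` pixel, by row/column
#' decomposition: per column, the distance to the nearest marked row
#' (sorted one-dimensional nearest neighbour); then per row, an exact
#' minimisation over columns of the combined squared distance. All pixels
#' of an empty mask get `Inf`.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of Euclidean distances in pixels.
#' @export
distance_transform <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(Inf, nr, nc))
  # phase 1: per-column vertical distance to nearest marked pixel
  d1 <- matrix(Inf, nr, nc)
  rows <- seq_len(nr)
  for (j in seq_len(nc)) {
    mr <- which(mask[, j])
    if (!length(mr)) next
    idx <- findInterval(rows, mr)
    lo <- ifelse(idx >= 1L, abs(rows - mr[pmax(idx, 1L)]), Inf)
    hi <- ifelse(idx < length(mr), abs(mr[pmin(idx + 1L, length(mr))] - rows), Inf)
    d1[, j] <- pmin(lo, hi)
  }
  # phase 2: minimise d1[,b]^2 + (col - b)^2 over source columns b
  d1sq <- d1^2
  cols <- seq_len(nc)
  out <- matrix(Inf, nr, nc)
  for (b in seq_len(nc)) {
    src <- d1sq[, b]
    if (all(!is.finite(src))) next
    out <- pmin(out, outer(src, (cols - b)^2, `+`))
  }
  sqrt(out)
}
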