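#' Luminance image with angular-resolution metadata
#'
#' A 2-D grid of photometric luminance (cd/m^2) plus the pixels-per-degree
#' of visual angle at which it is viewed. The angular resolution is
#' semantically required by every downstream step (band frequencies and
#' match-distance falloff are specified in visual angle), so it is carried
#' with the pixels and never guessed.
#'
#' @param values Numeric matrix of luminances, finite and non-negative.
#' @param ppd Pixels per degree of visual angle (positive scalar).
#' @param provenance `"synthetic"` or `"loaded"`.
#' @return An object of class `luminance_image`.
#' @export
luminance_image <- function(values, ppd, provenance = "synthetic") {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("luminances must be finite and non-negative", call. = FALSE)
  if (!is.numeric(ppd) || length(ppd) != 1L || !is.finite(ppd) || ppd <= 0)
    stop("`ppd` (pixels per degree) must be a positive scalar", call. = FALSE)
  provenance <- match.arg(provenance, c("synthetic", "loaded"))
  structure(list(values = values, ppd = ppd, provenance = provenance),
            class = "luminance_image")
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("Luminance image: %d x %d px, %.2f px/degree (%s)\n",
              nrow(x$values), ncol(x$values), x$ppd, x$provenance))
  cat(sprintf("  range %.4g - %.4g cd/m^2, mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.luminance_image <- function(x) dim(x$values)

# ---- HDR / mask image I/O ---------------------------------------------------

#' Read and write luminance images
#'
#' Supported formats: PFM (portable float map, grayscale `Pf`), float TIFF,
#' and 8/16-bit PNG. PFM and TIFF store luminance directly. PNG is an
#' integer display format, so PNG files are paired with a YAML sidecar
#' (`<file>.yaml`) recording the cd/m^2 value of full-scale white; the
#' sidecar also stores `ppd` for all formats.
#'
#' @param path File path; format chosen by extension (.pfm, .tif/.tiff,
#'   .png).
#' @param ppd Pixels per degree. For writing. For reading, taken from the
#'   sidecar unless overridden here; an error is raised when unavailable,
#'   never guessed.
#' @return `read_luminance_image()` returns a [luminance_image()];
#'   `write_luminance_image()` returns `path` invisibly.
#' @export
read_luminance_image <- function(path, ppd = NULL) {
  ext <- tolower(tools::file_ext(path))
  side <- read_sidecar(path)
  if (is.null(ppd)) ppd <- side$ppd
  if (is.null(ppd))
    stop("pixels-per-degree metadata not found for '", path,
         "': supply `ppd` or provide a YAML sidecar", call. = FALSE)
  values <- switch(ext,
    pfm = read_pfm(path),
    tif = ,
    tiff = {
      m <- tiff::readTIFF(path, as.is = FALSE)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      # TIFF is stored normalised to [0,1]; the sidecar records full scale
      if (!is.null(side$white_cdm2)) m <- m * side$white_cdm2
      m
    },
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      # without calibration metadata PNG values stay relative in [0,1]
      if (!is.null(side$white_cdm2)) m <- m * side$white_cdm2
      m
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  luminance_image(values, ppd = ppd, provenance = "loaded")
}

#' @param img A [luminance_image()].
#' @param white_cdm2 For PNG only: luminance mapped to full scale
#'   (default: the image maximum).
#' @rdname read_luminance_image
#' @export
write_luminance_image <- function(img, path, white_cdm2 = NULL) {
  stopifnot(inherits(img, "luminance_image"))
  ext <- tolower(tools::file_ext(path))
  side <- list(ppd = img$ppd)
  if (!is.null(white_cdm2)) side$white_cdm2 <- white_cdm2
  switch(ext,
    pfm = write_pfm(img$values, path),
    tif = ,
    tiff = tiff::writeTIFF(img$values / max(img$values, 1), path,
                           bits.per.sample = 32L),
    png = {
      if (is.null(white_cdm2)) white_cdm2 <- max(img$values, 1e-12)
      side$white_cdm2 <- white_cdm2
      png::writePNG(pmin(1, img$values / white_cdm2), path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (ext %in% c("tif", "tiff"))
    side$white_cdm2 <- max(img$values, 1)  # TIFF stored normalised to [0,1]
  write_sidecar(path, side)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) yaml::read_yaml(sp) else list()
}

write_sidecar <- function(path, fields) {
  yaml::write_yaml(fields, sidecar_path(path))
}

# PFM: "Pf\n<w> <h>\n<scale>\n" then w*h float32, rows bottom-to-top.
# Negative scale marks little-endian data.
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (grepl("[[:space:]]", ch)) { if (length(tok)) break else next }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (magic != "Pf") stop("only grayscale PFM ('Pf') is supported", call. = FALSE)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  scale <- as.numeric(read_token())
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = w * h, size = 4L, endian = endian)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m <- m[h:1, , drop = FALSE] * abs(scale)  # PFM rows run bottom-to-top
  m
}

write_pfm <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(values); w <- ncol(values)
  writeChar(sprintf("Pf\n%d %d\n-1.0\n", w, h), con, eos = NULL)
  flipped <- values[h:1, , drop = FALSE]
  writeBin(as.numeric(t(flipped)), con, size = 4L, endian = "little")
  invisible(path)
}
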