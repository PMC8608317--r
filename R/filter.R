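# Band-threshold simulation of low-vision appearance.
#
# The image is split into log-spaced band-pass components in the frequency
# domain (a cosine-log pyramid, which reconstructs exactly by summation).
# Per band, band-limited local contrast is the ratio of the band image to
# the low-pass image below it; pixels whose contrast magnitude falls below
# the observer's CSF threshold at the band's centre frequency are removed,
# and bands centred at or beyond the acuity cutoff are removed entirely.

mirror_pad <- function(m, pad_r, pad_c = pad_r) {
  nr <- nrow(m); nc <- ncol(m)
  pad_r <- min(pad_r, nr - 1L); pad_c <- min(pad_c, nc - 1L)
  ri <- c((pad_r + 1L):2L, 1L:nr, (nr - 1L):(nr - pad_r))
  ci <- c((pad_c + 1L):2L, 1L:nc, (nc - 1L):(nc - pad_c))
  list(m = m[ri, ci, drop = FALSE], pad_r = pad_r, pad_c = pad_c)
}

crop_pad <- function(m, pad_r, pad_c, nr, nc) {
  m[(pad_r + 1L):(pad_r + nr), (pad_c + 1L):(pad_c + nc), drop = FALSE]
}

# Radial spatial-frequency map (cycles/degree) for an FFT grid.
fft_radial_freq <- function(nr, nc, ppd) {
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  sqrt(outer(fr^2, fc^2, `+`)) * ppd
}

band_centers <- function(ppd, n_bands = NULL, octave_spacing = 1,
                         min_center = 0.35) {
  nyquist <- ppd / 2
  top <- nyquist / 2
  if (is.null(n_bands)) {
    n_bands <- max(1L, floor(log2(top / min_center) / octave_spacing) + 1L)
  }
  centers <- top / 2^(octave_spacing * (0:(n_bands - 1L)))
  if (max(centers) > nyquist)
    stop("highest band center frequency exceeds the Nyquist limit (",
         nyquist, " cpd)", call. = FALSE)
  centers
}

#' Decompose a luminance image into log-spaced frequency bands
#'
#' Cosine-log band-pass pyramid computed in the frequency domain on a
#' mirror-padded copy of the image (padding suppresses wrap-around
#' artifacts). Each band has a centre frequency in cycles/degree; centres
#' descend from Nyquist/2 in steps of `octave_spacing` octaves. The raised
#' cosine profiles form a partition of unity, so the bands plus the
#' residual low-pass baseband reconstruct the input exactly (to floating
#' point); residual energy above the top centre is folded into the top band
#' and below the bottom centre into the baseband.
#'
#' @param img A [luminance_image()].
#' @param n_bands Number of bands, or `NULL` to cover all octaves from
#'   Nyquist/2 down to `min_center`.
#' @param octave_spacing Band spacing in octaves (default 1).
#' @param min_center Lowest band centre frequency in cycles/degree used
#'   when `n_bands` is `NULL`. Structure coarser than this stays in the
#'   (unfiltered) baseband.
#' @return An object of class `band_stack`: list of band matrices with
#'   centre frequencies (cpd), a baseband matrix, and the source metadata.
#' @export
decompose_bands <- function(img, n_bands = NULL, octave_spacing = 1,
                            min_center = 0.35) {
  stopifnot(inherits(img, "luminance_image"))
  centers <- band_centers(img$ppd, n_bands, octave_spacing, min_center)
  nr <- nrow(img$values); nc <- ncol(img$values)
  padded <- mirror_pad(img$values, ceiling(nr / 2), ceiling(nc / 2))
  pr <- nrow(padded$m); pc <- ncol(padded$m)
  r <- fft_radial_freq(pr, pc, img$ppd)
  l <- matrix(-Inf, pr, pc)
  l[r > 0] <- log2(r[r > 0])

  F <- stats::fft(padded$m)
  filters <- lapply(log2(centers), function(lc) {
    d <- abs(l - lc) / octave_spacing
    g <- matrix(0, pr, pc)
    idx <- d < 1
    g[idx] <- 0.5 * (1 + cos(pi * d[idx]))
    g
  })
  total <- Reduce(`+`, filters)
  resid <- pmax(0, 1 - total)
  # complete the top band upward and the baseband downward
  hi <- l > log2(max(centers))
  filters[[1L]] <- filters[[1L]] + resid * hi
  baseband_f <- resid * (!hi)

  to_space <- function(g) {
    crop_pad(Re(stats::fft(F * g, inverse = TRUE)) / (pr * pc),
             padded$pad_r, padded$pad_c, nr, nc)
  }
  bands <- lapply(filters, to_space)
  baseband <- to_space(baseband_f)

  structure(list(bands = bands, centers = centers, baseband = baseband,
                 ppd = img$ppd, provenance = img$provenance),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  cat(sprintf("Band stack: %d bands at %s cpd + baseband (%d x %d px)\n",
              length(x$bands), paste(signif(x$centers, 3), collapse = ", "),
              nrow(x$baseband), ncol(x$baseband)))
  invisible(x)
}

#' Reconstruct the image from a band stack
#'
#' @param stack A [decompose_bands()] result.
#' @return The summed matrix (baseband plus all bands).
#' @export
reconstruct_bands <- function(stack) {
  stopifnot(inherits(stack, "band_stack"))
  Reduce(`+`, stack$bands, stack$baseband)
}

#' Band-limited local contrast
#'
#' Pointwise ratio of a band image to the low-pass image beneath it, the
#' standard band-limited contrast definition. The denominator is floored at
#' a small positive luminance so the ratio stays finite.
#'
#' @param band Band image (matrix).
#' @param lowpass Low-pass image below the band (matrix, same shape).
#' @param eps Luminance floor for the denominator, cd/m^2 (default 1e-6).
#' @return Matrix of local contrast values (dimensionless, finite).
#' @export
band_contrast <- function(band, lowpass, eps = 1e-6) {
  if (!identical(dim(band), dim(lowpass)))
    stop("band and lowpass grids must be aligned", call. = FALSE)
  band / pmax(lowpass, eps)
}

#' Apply a low-vision CSF threshold filter to a luminance image
#'
#' Simulates the loss of sub-threshold detail: the image is decomposed into
#' frequency bands, band-limited local contrast is compared per pixel with
#' the observer's threshold contrast at the band's centre frequency, and
#' only above-threshold content is retained. Bands centred at or above the
#' CSF cutoff frequency are removed entirely. The output is resynthesised
#' from the retained content plus the untouched baseband and clamped at
#' zero luminance.
#'
#' @param img A [luminance_image()].
#' @param csf A [build_csf()] object.
#' @param stack Optional precomputed [decompose_bands()] stack for `img`
#'   (saves the forward transform when filtering one scene for several
#'   observers).
#' @param soft If `TRUE`, a smooth contrast-gain ramp replaces the hard
#'   keep/zero rule (default `FALSE`: content is binary kept or removed).
#' @param softness Width of the soft ramp in log10 contrast units.
#' @param eps Luminance floor for contrast denominators (cd/m^2).
#' @param ... Passed to [decompose_bands()] when `stack` is missing.
#' @return A [luminance_image()] of the filtered scene. The attribute
#'   `kept_band_pixels` records, per band, how many pixels carried
#'   above-threshold contrast (removed bands count zero).
#' @export
apply_lowvision_filter <- function(img, csf, stack = NULL, soft = FALSE,
                                   softness = 0.2, eps = 1e-6, ...) {
  stopifnot(inherits(img, "luminance_image"), inherits(csf, "csf"))
  if (is.null(stack)) stack <- decompose_bands(img, ...)
  stopifnot(inherits(stack, "band_stack"))

  out <- stack$baseband
  lowpass <- stack$baseband
  kept <- integer(length(stack$bands))
  names(kept) <- signif(stack$centers, 4)
  # iterate coarse -> fine so `lowpass` accumulates everything below a band
  for (k in rev(seq_along(stack$bands))) {
    band <- stack$bands[[k]]
    fc <- stack$centers[k]
    if (fc < csf$cutoff_frequency) {
      thr <- contrast_threshold(csf, fc)
      contrast <- abs(band_contrast(band, lowpass, eps = eps))
      if (soft) {
        w <- stats::plogis((log10(pmax(contrast, 1e-12)) - log10(thr)) / softness)
      } else {
        w <- (contrast >= thr) * 1
      }
      kept[k] <- sum(contrast >= thr)
      out <- out + band * w
    }
    lowpass <- lowpass + band
  }
  res <- luminance_image(pmax(out, 0), ppd = img$ppd,
                         provenance = img$provenance)
  attr(res, "kept_band_pixels") <- kept
  res
}
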