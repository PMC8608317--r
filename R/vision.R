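#' Clinical vision parameters
#'
#' Bundle an observer's clinical visual acuity (logMAR) and Pelli-Robson
#' contrast sensitivity into a validated object. When the Pelli-Robson score
#' is unavailable (as it often is for severe acuity loss, where the chart's
#' letters fall below the resolution limit) it is inferred from acuity via
#' [infer_cs_from_acuity()] and flagged as such.
#'
#' @param acuity Visual acuity in logMAR units (0 = 20/20; higher = worse).
#'   Values outside the clinically plausible range \[-0.3, 2.5\] raise a
#'   warning; the model was validated for 0.8--1.66 logMAR.
#' @param cs Pelli-Robson contrast sensitivity (log10 units, higher =
#'   better), or `NULL` to infer it from acuity.
#' @return An object of class `vision_params` with fields `acuity`, `cs`
#'   `cs_source` (`"measured"` or `"inferred-from-acuity"`), and the
#'   convenience flag `cs_inferred`.
#' @examples
#' vision_params(1.2, 0.68)       # moderate acuity reduction
#' vision_params(1.62)            # CS inferred: 1.72 - 0.69 * 1.62 = 0.60
#' @export
vision_params <- function(acuity, cs = NULL) {
  if (!is.numeric(acuity) || length(acuity) != 1L || !is.finite(acuity))
    stop("`acuity` must be a single finite numeric (logMAR)", call. = FALSE)
  if (acuity < -0.3 || acuity > 2.5)
    warning("acuity ", acuity, " logMAR is outside the supported range [-0.3, 2.5]")
  if (is.null(cs)) {
    cs <- infer_cs_from_acuity(acuity)
    cs_source <- "inferred-from-acuity"
    message("Pelli-Robson CS not supplied; inferred from acuity: ", round(cs, 2))
  } else {
    if (!is.numeric(cs) || length(cs) != 1L || !is.finite(cs))
      stop("`cs` must be a single finite numeric (Pelli-Robson log units)",
           call. = FALSE)
    if (cs < 0 || cs > 2.5)
      warning("contrast sensitivity ", cs, " is outside the supported range [0, 2.5]")
    cs_source <- "measured"
  }
  structure(list(acuity = acuity, cs = cs, cs_source = cs_source,
                 cs_inferred = cs_source == "inferred-from-acuity"),
            class = "vision_params")
}

#' @export
print.vision_params <- function(x, ...) {
  cat("Vision parameters\n")
  cat(sprintf("  acuity:               %.2f logMAR\n", x$acuity))
  cat(sprintf("  contrast sensitivity: %.2f Pelli-Robson log units (%s)\n",
              x$cs, x$cs_source))
  invisible(x)
}

#' Infer Pelli-Robson contrast sensitivity from logMAR acuity
#'
#' Linear clinical relationship `CS = 1.72 - 0.69 * VA` between Pelli-Robson
#' log contrast sensitivity and logMAR acuity, used when CS cannot be
#' measured directly. The result is clamped below at 0 (a negative log
#' sensitivity would mean threshold contrast above 100%).
#'
#' @param acuity logMAR visual acuity (finite scalar or vector).
#' @return Pelli-Robson contrast sensitivity, same length as `acuity`.
#' @examples
#' infer_cs_from_acuity(1.62)  # 0.6022 -> the severe-group mean 0.60
#' infer_cs_from_acuity(0)     # 1.72, the intercept
#' @export
infer_cs_from_acuity <- function(acuity) {
  if (!is.numeric(acuity) || length(acuity) < 1L || any(!is.finite(acuity)))
    stop("`acuity` must be finite numeric (logMAR)", call. = FALSE)
  pmax(0, 1.72 - 0.69 * acuity)
}

#' Construct a contrast sensitivity function from clinical parameters
#'
#' Builds a parametric CSF -- log-parabolic in (log10 frequency,
#' log10 sensitivity), the standard template shape -- positioned by two
#' anchors derived from the clinical measures:
#'
#' * **Acuity anchor.** Sensitivity falls to 1 (threshold contrast 100%) at
#'   the cutoff frequency `f0 * 10^-acuity`. With the default `f0 = 30`
#'   cycles/degree this is the conventional letter-acuity cutoff: logMAR 0
#'   maps to 30 cpd, each logMAR unit of loss shifts the cutoff one log
#'   unit leftward.
#' * **Sensitivity anchor.** Sensitivity equals `10^cs` at the anchor
#'   frequency `f_ref * 10^-acuity`. The anchor frequency shifts together
#'   with the cutoff, so the whole template translates rigidly along the
#'   log-frequency axis with acuity and moves down with decreasing CS --
#'   the shifted-template account of low-vision CSFs. At logMAR 0 the
#'   anchor sits at `f_ref` (default 1 cpd), i.e. S(1 cpd) = 10^CS.
#'
#' With the parabola's curvature fixed by `bandwidth`, the two anchors
#' determine the peak frequency and peak sensitivity uniquely, with the
#' peak always below the cutoff.
#'
#' @param params A [vision_params()] object.
#' @param f0 Cutoff frequency (cycles/degree) at logMAR 0. Default 30.
#' @param f_ref Sensitivity-anchor frequency (cycles/degree) at logMAR 0.
#'   Default 1 (the Pelli-Robson chart probes low spatial frequencies).
#'   Must be below `f0`.
#' @param bandwidth Template half-width: log10-frequency distance over which
#'   log sensitivity falls by 1 from the peak of a unit-height parabola.
#'   Default 0.65, giving a normal observer (logMAR 0, CS 2.0) a peak
#'   sensitivity near 300 at about 2.8 cpd.
#' @return An object of class `csf` with fields `peak_sensitivity`,
#'   `peak_frequency`, `cutoff_frequency`, `bandwidth` and the anchor
#'   record.
#' @examples
#' csf <- build_csf(vision_params(0, 2.0))
#' csf$cutoff_frequency  # 30 cpd
#' @export
build_csf <- function(params, f0 = 30, f_ref = 1, bandwidth = 0.65) {
  stopifnot(inherits(params, "vision_params"))
  if (!is.finite(f0) || f0 <= 0 || !is.finite(f_ref) || f_ref <= 0)
    stop("`f0` and `f_ref` must be positive and finite", call. = FALSE)
  if (f_ref >= f0)
    stop("CSF anchors unsatisfiable: the sensitivity-anchor frequency f_ref (",
         f_ref, " cpd) must lie below the acuity-cutoff scale f0 (", f0,
         " cpd), otherwise the anchor falls at or beyond the cutoff",
         call. = FALSE)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be positive", call. = FALSE)

  cs <- max(0, params$cs)
  x_cut <- log10(f0) - params$acuity       # log10 cutoff frequency
  x_anchor <- log10(f_ref) - params$acuity # log10 sensitivity-anchor frequency
  a <- (x_cut - x_anchor) / bandwidth      # anchor separation in template units
  # Solve for the parabola through (x_anchor, cs) and (x_cut, 0):
  # log10 S(x) = u^2 - ((x - m)/w + u - a ... ) ; closed form below.
  u <- (cs + a^2) / (2 * a)                # (x_cut - peak) / bandwidth
  peak_log_s <- u^2
  peak_log_f <- x_cut - bandwidth * u

  structure(list(
    peak_sensitivity = 10^peak_log_s,
    peak_frequency   = 10^peak_log_f,
    cutoff_frequency = 10^x_cut,
    bandwidth        = bandwidth,
    anchor_frequency = 10^x_anchor,
    anchor_sensitivity = 10^cs,
    f0 = f0, f_ref = f_ref,
    params = params
  ), class = "csf")
}

#' @export
print.csf <- function(x, ...) {
  cat("Contrast sensitivity function (log-parabola template)\n")
  cat(sprintf("  peak sensitivity: %.1f at %.3f cpd\n",
              x$peak_sensitivity, x$peak_frequency))
  cat(sprintf("  cutoff frequency: %.3f cpd\n", x$cutoff_frequency))
  cat(sprintf("  anchored: S(%.3f cpd) = %.2f; bandwidth %.2f log10 units\n",
              x$anchor_frequency, x$anchor_sensitivity, x$bandwidth))
  invisible(x)
}

#' Evaluate contrast sensitivity at given spatial frequencies
#'
#' @param csf A [build_csf()] object.
#' @param f Spatial frequency in cycles/degree (vectorised, `>= 0`).
#' @return Linear contrast sensitivity `S(f) > 0`; `S(f) = 0` at `f = 0`.
#' @export
csf_sensitivity <- function(csf, f) {
  stopifnot(inherits(csf, "csf"))
  if (any(f < 0, na.rm = TRUE)) stop("frequencies must be >= 0", call. = FALSE)
  s <- numeric(length(f))
  pos <- is.finite(f) & f > 0
  lx <- (log10(f[pos]) - log10(csf$peak_frequency)) / csf$bandwidth
  s[pos] <- 10^(log10(csf$peak_sensitivity) - lx^2)
  s
}

#' Threshold contrast at a spatial frequency
#'
#' The Michelson contrast needed to detect a grating of frequency `f`:
#' the reciprocal of the CSF. At and above the cutoff frequency the
#' threshold is at least 1 (100% contrast), i.e. nothing is visible.
#'
#' @inheritParams csf_sensitivity
#' @return Threshold contrast (dimensionless, vectorised); `Inf` at `f = 0`
#'   or wherever sensitivity underflows.
#' @export
contrast_threshold <- function(csf, f) {
  s <- csf_sensitivity(csf, f)
  thr <- ifelse(s > 0, 1 / s, Inf)
  # At/beyond cutoff nothing is visible regardless of template tail values.
  thr[f >= csf$cutoff_frequency] <- pmax(thr[f >= csf$cutoff_frequency], 1)
  thr
}
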