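# Validation statistics: logistic regression of identification accuracy on
# HVS, deviance accounting, likelihood-ratio and Chow tests, HVS binning,
# slope-versus-vision meta-regression, and a simulated forced-choice
# observer for parameter-recovery studies.

#' Fit the accuracy-versus-HVS logistic model
#'
#' Maximum-likelihood logistic regression (logit link, IRLS via
#' [stats::glm()]) of a binary correct/incorrect response on the Hazard
#' Visibility Score: `ln(P/(1-P)) = A*X + B`. Reports the slope `A` with
#' its 95% Wald confidence interval, the null and residual deviances, and
#' the reduced deviance ratio `(D0 - Dr)/D0` (the fraction of binomial
#' deviance explained by HVS). Complete separation is flagged, not silently
#' returned as a divergent fit.
#'
#' @param data Data frame of trials.
#' @param hvs_col,correct_col Column names of the HVS predictor (in
#'   `[0, 1]`) and binary outcome.
#' @param conf_level Confidence level for the slope interval.
#' @param random_intercept If `TRUE`, adds a per-subject random intercept
#'   via `lme4::glmer` (requires a `subject` column); the default pooled
#'   fixed-effect fit is used otherwise.
#' @return An object of class `hvs_logit`.
#' @export
fit_hvs_logistic <- function(data, hvs_col = "hvs", correct_col = "correct",
                             conf_level = 0.95, random_intercept = FALSE) {
  if (!is.data.frame(data) || !all(c(hvs_col, correct_col) %in% names(data)))
    stop("`data` must contain columns '", hvs_col, "' and '", correct_col,
         "'", call. = FALSE)
  x <- data[[hvs_col]]
  y <- data[[correct_col]]
  if (length(x) < 2L) stop("need at least 2 trials", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("HVS values must be finite and in [0, 1]", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("responses must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("only one outcome class present: the logistic model is undefined",
         call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate design: HVS is constant across trials, slope undefined",
         call. = FALSE)

  if (random_intercept) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("`random_intercept = TRUE` requires the lme4 package",
           call. = FALSE)
    if (!"subject" %in% names(data))
      stop("`random_intercept = TRUE` requires a `subject` column",
           call. = FALSE)
    df <- data.frame(x = x, y = y, subject = factor(data$subject))
    fit <- lme4::glmer(y ~ x + (1 | subject), data = df, family = binomial())
    A <- lme4::fixef(fit)[["x"]]; B <- lme4::fixef(fit)[["(Intercept)"]]
    se_A <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
    d0 <- NA_real_; dr <- stats::deviance(fit)
    warned <- FALSE
  } else {
    df <- data.frame(x = x, y = y)
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    A <- stats::coef(fit)[["x"]]; B <- stats::coef(fit)[["(Intercept)"]]
    se_A <- sqrt(diag(stats::vcov(fit)))[["x"]]
    d0 <- fit$null.deviance; dr <- stats::deviance(fit)
  }
  separated <- warned || abs(A) > 1e3 || !is.finite(se_A) || se_A > 1e3
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    slope = A, intercept = B,
    slope_se = se_A,
    slope_ci = c(A - zq * se_A, A + zq * se_A),
    conf_level = conf_level,
    null_deviance = d0, residual_deviance = dr,
    reduced_deviance_ratio = if (is.finite(d0) && d0 > 0) (d0 - dr) / d0
                             else NA_real_,
    n = length(y),
    converged = if (random_intercept) TRUE else fit$converged && !separated,
    separation = separated,
    random_intercept = random_intercept,
    fit = fit
  ), class = "hvs_logit")
}

#' @export
print.hvs_logit <- function(x, digits = 3, ...) {
  cat("Logistic model of identification accuracy on HVS\n")
  cat(sprintf("  n = %d trials%s\n", x$n,
              if (x$random_intercept) " (per-subject random intercept)" else ""))
  cat(sprintf("  slope A = %.*f  [%.*f, %.*f] (%.0f%% CI), intercept B = %.*f\n",
              digits, x$slope, digits, x$slope_ci[1], digits, x$slope_ci[2],
              100 * x$conf_level, digits, x$intercept))
  if (is.finite(x$null_deviance))
    cat(sprintf("  deviance: null %.2f, residual %.2f, reduced ratio %.1f%%\n",
                x$null_deviance, x$residual_deviance,
                100 * x$reduced_deviance_ratio))
  if (x$separation)
    cat("  WARNING: complete or quasi-complete separation detected\n")
  invisible(x)
}

#' @export
summary.hvs_logit <- function(object, ...) {
  print(object, ...)
  lr <- lr_test_vs_null(object)
  cat(sprintf("  LR test vs intercept-only null: chi-sq(%d) = %.2f, p = %.3g\n",
              lr$df, lr$statistic, lr$p_value))
  invisible(object)
}

#' @export
coef.hvs_logit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
confint.hvs_logit <- function(object, parm = "slope", level = NULL, ...) {
  object$slope_ci
}

#' @export
predict.hvs_logit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$fit$model$x
       else if (is.data.frame(newdata)) newdata[[1L]]
       else newdata
  predicted_probability(object, x)
}

#' Predicted probability of correct identification
#'
#' The logistic transform `P = exp(A*X + B) / (exp(A*X + B) + 1)` of the
#' fitted linear predictor.
#'
#' @param fit An `hvs_logit` fit (or any list with `slope` and
#'   `intercept`).
#' @param x HVS values (vectorised).
#' @return Probabilities in `(0, 1)`.
#' @export
predicted_probability <- function(fit, x) {
  stats::plogis(fit$slope * x + fit$intercept)
}

#' Likelihood-ratio test against the intercept-only null model
#'
#' Chi-square test on the deviance drop `D0 - Dr` with 1 degree of
#' freedom (the HVS slope).
#'
#' @param fit An `hvs_logit` fit with valid deviances.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lr_test_vs_null <- function(fit) {
  stopifnot(inherits(fit, "hvs_logit"))
  if (!is.finite(fit$null_deviance))
    stop("null deviance unavailable for this fit", call. = FALSE)
  stat <- max(0, fit$null_deviance - fit$residual_deviance)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Chow test for equality of two accuracy-versus-HVS models
#'
#' Tests whether two samples share one set of accuracy-versus-HVS
#' coefficients against separate per-sample fits, via the Chow F statistic
#' `F = ((RSS_p - RSS_1 - RSS_2)/k) / ((RSS_1 + RSS_2)/(n1 + n2 - 2k))`
#' with `k = 2` parameters. The default `"lpm"` is the classical test on a
#' linear probability model (ordinary least squares of the 0/1 outcome on
#' HVS), for which the F reference distribution is the standard one.
#' `method = "deviance"` substitutes logistic-regression deviances for the
#' residual sums of squares, giving an analogous F-like statistic for the
#' logistic law itself. Sums of squared Pearson residuals are *not*
#' offered: for ungrouped binary outcomes the Pearson chi-square of any
#' fitted logistic model is close to `n` by construction, so pooled and
#' separate fits cancel and the statistic carries no information.
#'
#' @param trials_1,trials_2 Trial data frames (see [fit_hvs_logistic()]).
#' @param method `"lpm"` (default) or `"deviance"`.
#' @inheritParams fit_hvs_logistic
#' @return An object of class `chow_result`: `statistic`, `df` (length 2),
#'   `p_value`, `method`.
#' @export
chow_test <- function(trials_1, trials_2, method = c("lpm", "deviance"),
                      hvs_col = "hvs", correct_col = "correct") {
  method <- match.arg(method)
  k <- 2L
  n1 <- nrow(trials_1); n2 <- nrow(trials_2)
  df2 <- n1 + n2 - 2L * k
  if (df2 <= 0) stop("samples too small for the Chow test", call. = FALSE)
  pooled <- rbind(trials_1[, c(hvs_col, correct_col)],
                  trials_2[, c(hvs_col, correct_col)])
  rss <- function(d) {
    x <- d[[hvs_col]]; y <- d[[correct_col]]
    if (method == "deviance") {
      stats::glm(y ~ x, family = stats::binomial())$deviance
    } else {
      f <- stats::lm(y ~ x)
      sum(stats::residuals(f)^2)
    }
  }
  r1 <- rss(trials_1); r2 <- rss(trials_2); rp <- rss(pooled)
  Fstat <- max(0, ((rp - r1 - r2) / k) / ((r1 + r2) / df2))
  structure(list(statistic = Fstat, df = c(k, df2),
                 p_value = stats::pf(Fstat, k, df2, lower.tail = FALSE),
                 method = method),
            class = "chow_result")
}

#' @export
print.chow_result <- function(x, ...) {
  cat(sprintf("Chow test (%s): F(%d, %d) = %.2f, p = %.3g\n",
              x$method, x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}

#' Bin trials by HVS
#'
#' Ten (by default) half-open bins `[0, 0.1), ..., [0.9, 1.0]`, the last
#' bin closed above, with per-bin counts of correct and incorrect trials.
#'
#' @param data Trial data frame.
#' @inheritParams fit_hvs_logistic
#' @param bin_width Bin width; must divide 1 evenly (default 0.1).
#' @return Data frame with `bin_lo`, `bin_hi`, `n_correct`, `n_incorrect`,
#'   `n`; bin counts sum to `nrow(data)`.
#' @export
bin_trials <- function(data, bin_width = 0.1, hvs_col = "hvs",
                       correct_col = "correct") {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("`bin_width` must divide 1 evenly", call. = FALSE)
  nb <- as.integer(round(nb))
  x <- data[[hvs_col]]; y <- data[[correct_col]]
  bin <- pmin(nb, floor(x / bin_width) + 1L)  # [0,w), ..., last closed at 1
  lo <- (seq_len(nb) - 1L) * bin_width
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_width)
  out$n_correct <- as.integer(tabulate(bin[y == 1], nbins = nb))
  out$n_incorrect <- as.integer(tabulate(bin[y == 0], nbins = nb))
  out$n <- out$n_correct + out$n_incorrect
  out
}

#' Regress per-subject logistic slopes on a vision measure
#'
#' Ordinary least squares of the per-subject accuracy-versus-HVS slopes on
#' a clinical vision variable (logMAR acuity or Pelli-Robson contrast
#' sensitivity), quantifying how the predictive power of the visibility
#' score varies with severity of vision loss.
#'
#' @param slopes Numeric vector of per-subject logistic slopes.
#' @param vision Numeric vector of the vision measure, same length.
#' @return An object of class `vision_slope_fit` with `slope`, `intercept`
#'   and `r_squared`.
#' @export
slope_vs_vision_regression <- function(slopes, vision) {
  if (length(slopes) != length(vision) || length(slopes) < 3L)
    stop("need >= 3 paired (slope, vision) observations", call. = FALSE)
  if (stats::var(vision) == 0)
    stop("vision measure has zero variance", call. = FALSE)
  f <- stats::lm(slopes ~ vision)
  # R^2 computed directly so that an exactly collinear input (legitimate
  # here, e.g. a noiseless check) does not trigger summary.lm's warning
  tss <- sum((slopes - mean(slopes))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(f)^2) / tss else NA_real_
  structure(list(slope = unname(stats::coef(f)[2]),
                 intercept = unname(stats::coef(f)[1]),
                 r_squared = r2,
                 fit = f),
            class = "vision_slope_fit")
}

#' @export
print.vision_slope_fit <- function(x, ...) {
  cat(sprintf("OLS: slope = %.2f, intercept = %.2f, R^2 = %.2f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Simulate a forced-choice observer
#'
#' Responses are Bernoulli with
#' `P(correct) = g + (1 - g) * plogis(A*X + B)`: the logistic
#' accuracy-versus-visibility law with an optional guessing floor `g`
#' (chance in a five-alternative task is 0.2).
#'
#' @param hvs Vector of per-trial HVS values.
#' @param A,B Slope and intercept of the response model.
#' @param guess_floor Guessing floor `g` in `[0, 1)` (default 0).
#' @param seed Explicit integer seed (required, for reproducibility).
#' @return Data frame with columns `hvs`, `p`, `correct`.
#' @export
simulate_observer <- function(hvs, A, B, guess_floor = 0, seed) {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  if (guess_floor < 0 || guess_floor >= 1)
    stop("`guess_floor` must be in [0, 1)", call. = FALSE)
  p <- guess_floor + (1 - guess_floor) * stats::plogis(A * hvs + B)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(hvs = hvs, p = p, correct = stats::rbinom(length(hvs), 1L, p))
}

#' Bundled low-vision observer reference table
#'
#' Clinical characteristics and fitted accuracy-versus-HVS logistic slopes
#' for ten low-vision observers from a hazard-identification validation
#' experiment: logMAR acuity, Pelli-Robson contrast sensitivity, and the
#' per-observer slope, null deviance, residual deviance and reduced
#' deviance ratio.
#'
#' @return A data.frame with one row per observer.
#' @export
low_vision_subjects <- function() {
  path <- system.file("extdata", "low_vision_subjects.csv",
                      package = "hazvis", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
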