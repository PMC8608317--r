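# End-to-end orchestration: scene -> CSF filter -> luminance boundaries ->
# edge matching -> HVS, and the full synthetic validation experiment
# (factorial design, simulated observers, logistic fits).

#' Pipeline configuration
#'
#' Collects every tunable of the scoring pipeline and the validation
#' experiment. All stochastic steps derive their seeds deterministically
#' from `seed`. Configurations round-trip through YAML unchanged
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param image_size Rendered image height/width in pixels for experiment
#'   scenes (default 192; [render_scene()] keeps its own 512 default for
#'   single-scene work).
#' @param ppd Pixels per degree for experiment scenes (default 6, giving a
#'   32-degree field that contains the walkway and step).
#' @param n_bands,min_center,soft Band-decomposition and thresholding
#'   options, see [decompose_bands()] and [apply_lowvision_filter()].
#' @param canny_sigma,canny_low,canny_high Boundary-extraction parameters,
#'   see [detect_luminance_boundaries()].
#' @param d_max_deg,kernel Distance-to-score mapping, see
#'   [score_from_distance()].
#' @param roi Which ROI the experiment scores (default `"whole-step"`).
#' @param seed Master seed (integer).
#' @param groups Named list of observer groups for
#'   [run_validation_experiment()]; see [default_observer_groups()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(image_size = 192, ppd = 6,
                            n_bands = NULL, min_center = 0.35, soft = FALSE,
                            canny_sigma = 1.0, canny_low = 0.02,
                            canny_high = 0.05,
                            d_max_deg = 0.5, kernel = "linear",
                            roi = "whole-step", seed = 1L,
                            groups = default_observer_groups()) {
  if (!is.numeric(ppd) || ppd <= 0) stop("`ppd` must be positive",
                                         call. = FALSE)
  if (!is.numeric(image_size) || any(image_size < 8))
    stop("`image_size` must be at least 8 pixels", call. = FALSE)
  if (d_max_deg <= 0) stop("`d_max_deg` must be positive", call. = FALSE)
  kernel <- match.arg(kernel, c("linear", "exponential"))
  roi <- match.arg(roi, c("whole-step", "corners", "central-edge"))
  if (!(canny_low > 0 && canny_low < canny_high))
    stop("need 0 < canny_low < canny_high", call. = FALSE)
  cfg <- list(image_size = as.integer(image_size), ppd = ppd,
              n_bands = n_bands, min_center = min_center, soft = soft,
              canny_sigma = canny_sigma, canny_low = canny_low,
              canny_high = canny_high, d_max_deg = d_max_deg,
              kernel = kernel, roi = roi, seed = as.integer(seed),
              groups = groups)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Default observer groups for the validation experiment
#'
#' Two artificial-blur groups of seven observers each, mirroring the
#' moderate (mean 1.2 logMAR, SD 0.085; mean CS 0.68, SD 0.1) and severe
#' (mean 1.62 logMAR, SD 0.028; CS inferred from acuity) conditions of the
#' validation study. `slope`/`intercept` parameterise the simulated
#' response model; `guess_floor = 0.2` is chance in the five-alternative
#' task.
#'
#' @return Named list of group definitions.
#' @export
default_observer_groups <- function() {
  list(
    moderate = list(n_subjects = 7, acuity_mean = 1.2, acuity_sd = 0.085,
                    cs_mean = 0.68, cs_sd = 0.1, infer_cs = FALSE,
                    slope = 3.02, intercept = -1.0, guess_floor = 0.2),
    severe = list(n_subjects = 7, acuity_mean = 1.62, acuity_sd = 0.028,
                  cs_mean = NA, cs_sd = NA, infer_cs = TRUE,
                  slope = 1.54, intercept = -1.0, guess_floor = 0.2)
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (hash", config_hash(x), ")\n")
  flat <- x[setdiff(names(x), "groups")]
  for (nm in names(flat))
    cat(sprintf("  %-12s %s\n", nm,
                paste(format(flat[[nm]]), collapse = " ")))
  cat("  groups:      ", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "groups")])
  if (!is.null(raw$groups)) cfg$groups <- raw$groups
  cfg
}

#' Short stable identifier of a configuration (a polynomial rolling hash of
#' its serialised form), embedded in every output artifact.
#' @param cfg A [pipeline_config()].
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' Score a scene for an observer: the full HVS pipeline
#'
#' Runs filter -> boundary extraction -> edge matching -> scoring for one
#' scene and one observer, reporting the HVS of every ROI.
#'
#' @param x A [scene_spec()] (rendered on the fly), a [render_scene()]
#'   result, or a [luminance_image()] (then `geometry` is required).
#' @param vision A [vision_params()] object.
#' @param config A [pipeline_config()].
#' @param geometry For image input: an [edge_map()] of geometric edges.
#' @param rois For image input: named list of ROI masks (`NULL` scores all
#'   geometry pixels under the ROI label `"all"`).
#' @param stack Optional precomputed [decompose_bands()] stack.
#' @param out_dir If non-`NULL`, writes `hvs.csv` and an overlay PNG there.
#' @return An object of class `hvs_report`: `table` (data.frame with
#'   columns `roi`, `hvs`, `n_geometry_pixels`, `config_hash`), plus the
#'   intermediate `filtered` image, `boundaries` map and `distances`.
#' @export
run_hvs <- function(x, vision, config = pipeline_config(), geometry = NULL,
                    rois = NULL, stack = NULL, out_dir = NULL) {
  stopifnot(inherits(vision, "vision_params"),
            inherits(config, "pipeline_config"))
  if (inherits(x, "scene_spec")) x <- render_scene(x)
  if (inherits(x, "scene_render")) {
    img <- x$luminance
    geometry <- x$geometry_edges
    if (is.null(rois)) rois <- x$rois
  } else if (inherits(x, "luminance_image")) {
    img <- x
    if (is.null(geometry))
      stop("`geometry` edge map is required for image input", call. = FALSE)
    if (is.null(rois)) rois <- list(all = NULL)
  } else {
    stop("`x` must be a scene_spec, scene_render or luminance_image",
         call. = FALSE)
  }

  csf <- build_csf(vision)
  filtered <- apply_lowvision_filter(img, csf, stack = stack,
                                     soft = config$soft,
                                     n_bands = config$n_bands,
                                     min_center = config$min_center)
  boundaries <- detect_luminance_boundaries(filtered,
                                            sigma = config$canny_sigma,
                                            low = config$canny_low,
                                            high = config$canny_high)
  distances <- nearest_boundary_distances(geometry, boundaries)
  tab <- do.call(rbind, lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    inside <- if (is.null(roi)) rep(TRUE, nrow(distances))
              else roi[cbind(distances$row, distances$col)] > 0
    data.frame(roi = nm,
               hvs = hazard_visibility_score(distances, roi, ppd = img$ppd,
                                             d_max_deg = config$d_max_deg,
                                             kernel = config$kernel),
               n_geometry_pixels = sum(inside),
               config_hash = config_hash(config))
  }))
  rep <- structure(list(table = tab, filtered = filtered,
                        boundaries = boundaries, distances = distances,
                        config = config),
                   class = "hvs_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "hvs.csv"), row.names = FALSE)
    overlay <- render_visibility_overlay(img, distances,
                                         d_max_deg = config$d_max_deg)
    png::writePNG(overlay, file.path(out_dir, "overlay.png"))
  }
  rep
}

#' @export
print.hvs_report <- function(x, ...) {
  cat("Hazard Visibility Scores\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Run the synthetic validation experiment
#'
#' Builds the full factorial stimulus design, renders every unique scene,
#' computes per-trial HVS values for each simulated observer (observer
#' vision parameters drawn from the group definitions), simulates
#' forced-choice responses from the group response model, and fits the
#' validation statistics: per-subject and pooled logistic models,
#' likelihood-ratio tests, HVS bin counts and (with two groups) the Chow
#' test.
#'
#' @param config A [pipeline_config()].
#' @param n_reps Repetitions per design cell (default 2: 250 trials per
#'   subject).
#' @param progress Print per-scene progress.
#' @param out_dir If non-`NULL`, writes `trials.csv`, `subject_fits.csv`
#'   and `bins_<group>.csv` there.
#' @return An object of class `validation_experiment` with elements
#'   `trials`, `subjects`, `pooled` (per-group `hvs_logit` fits), `bins`,
#'   `chow` and `config`.
#' @export
run_validation_experiment <- function(config = pipeline_config(),
                                      n_reps = 2, progress = FALSE,
                                      out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- enumerate_design(n_reps = n_reps)
  scenes <- unique(design[, c("target", "lighting", "viewpoint")])
  scenes$scene_id <- seq_len(nrow(scenes))
  design <- merge(design, scenes, by = c("target", "lighting", "viewpoint"),
                  sort = FALSE)
  design <- design[order(design$trial), ]

  # draw observer panels
  subjects <- do.call(rbind, lapply(names(config$groups), function(gname) {
    g <- config$groups[[gname]]
    sseed <- derive_seed(config$seed, match(gname, names(config$groups)))
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(sseed)
    acu <- pmin(2.5, pmax(-0.3, stats::rnorm(g$n_subjects, g$acuity_mean,
                                             g$acuity_sd)))
    cs <- if (isTRUE(g$infer_cs)) infer_cs_from_acuity(acu)
          else pmin(2.5, pmax(0, stats::rnorm(g$n_subjects, g$cs_mean,
                                              g$cs_sd)))
    data.frame(subject = paste0(toupper(substr(gname, 1, 1)),
                                seq_len(g$n_subjects)),
               group = gname, acuity = acu, cs = cs,
               cs_source = if (isTRUE(g$infer_cs)) "inferred-from-acuity"
                           else "measured",
               slope_true = g$slope, intercept_true = g$intercept,
               guess_floor = g$guess_floor,
               stringsAsFactors = FALSE)
  }))

  # per-scene HVS for every subject (band stack shared across observers)
  hvs_mat <- matrix(NA_real_, nrow(scenes), nrow(subjects),
                    dimnames = list(NULL, subjects$subject))
  vp_list <- lapply(seq_len(nrow(subjects)), function(i)
    suppressWarnings(vision_params(subjects$acuity[i], subjects$cs[i])))
  for (s in seq_len(nrow(scenes))) {
    sp <- scene_spec(target = scenes$target[s], lighting = scenes$lighting[s],
                     viewpoint = scenes$viewpoint[s],
                     image_size = config$image_size, ppd = config$ppd)
    render <- render_scene(sp)
    stack <- decompose_bands(render$luminance, n_bands = config$n_bands,
                             min_center = config$min_center)
    roi <- render$rois[[config$roi]]
    for (i in seq_len(nrow(subjects))) {
      rep_i <- run_hvs(render, vp_list[[i]], config, stack = stack,
                       rois = stats::setNames(list(roi), config$roi))
      hvs_mat[s, i] <- rep_i$table$hvs[1]
    }
    if (progress) message("scene ", s, "/", nrow(scenes))
  }

  # assemble trials and simulate responses
  trials <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    x <- hvs_mat[design$scene_id, i]
    resp <- simulate_observer(x, A = subjects$slope_true[i],
                              B = subjects$intercept_true[i],
                              guess_floor = subjects$guess_floor[i],
                              seed = derive_seed(config$seed, 1000 + i))
    data.frame(subject = subjects$subject[i], group = subjects$group[i],
               design[, c("target", "lighting", "viewpoint", "repetition")],
               hvs = x, correct = resp$correct, stringsAsFactors = FALSE)
  }))
  rownames(trials) <- NULL

  # fits
  fit_row <- function(f) data.frame(
    slope = f$slope, slope_ci_lo = f$slope_ci[1], slope_ci_hi = f$slope_ci[2],
    null_deviance = f$null_deviance, residual_deviance = f$residual_deviance,
    reduced_deviance_ratio = f$reduced_deviance_ratio, n = f$n,
    lr_p = lr_test_vs_null(f)$p_value)
  subj_fits <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    tr <- trials[trials$subject == subjects$subject[i], ]
    cbind(subjects[i, c("subject", "group", "acuity", "cs")],
          fit_row(fit_hvs_logistic(tr)))
  }))
  rownames(subj_fits) <- NULL
  pooled <- lapply(split(trials, trials$group), fit_hvs_logistic)
  bins <- lapply(split(trials, trials$group), bin_trials)
  chow <- if (length(pooled) == 2L) {
    gs <- split(trials, trials$group)
    chow_test(gs[[1]], gs[[2]])
  } else NULL

  res <- structure(list(trials = trials, subjects = subj_fits,
                        pooled = pooled, bins = bins, chow = chow,
                        config = config),
                   class = "validation_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    h <- config_hash(config)
    tr_out <- trials; tr_out$config_hash <- h
    sf_out <- subj_fits; sf_out$config_hash <- h
    utils::write.csv(tr_out, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(sf_out, file.path(out_dir, "subject_fits.csv"),
                     row.names = FALSE)
    for (g in names(bins))
      utils::write.csv(cbind(bins[[g]], config_hash = h),
                       file.path(out_dir, paste0("bins_", g, ".csv")),
                       row.names = FALSE)
  }
  res
}

#' @export
print.validation_experiment <- function(x, ...) {
  cat(sprintf("Validation experiment: %d trials, %d subjects, %d group(s)\n",
              nrow(x$trials), nrow(x$subjects), length(x$pooled)))
  for (g in names(x$pooled)) {
    f <- x$pooled[[g]]
    cat(sprintf("  %-9s pooled slope %.2f [%.2f, %.2f], n = %d, ratio %.1f%%\n",
                g, f$slope, f$slope_ci[1], f$slope_ci[2], f$n,
                100 * f$reduced_deviance_ratio))
  }
  if (!is.null(x$chow)) print(x$chow)
  invisible(x)
}
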