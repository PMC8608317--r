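test_that("visual angle uses the full-angle convention", {
  expect_equal(round(visual_angle(7, 120), 1), 3.3)
  expect_equal(round(visual_angle(48, 120)), 23)
  expect_equal(visual_angle(0, 120), 0)
  expect_error(visual_angle(1, 0), "distance")
  expect_error(visual_angle(-1, 10), "extent")
})

test_that("factor enumerations have five levels each", {
  expect_length(scene_targets(), 5)
  expect_length(scene_lightings(), 5)
  expect_length(scene_viewpoints(), 5)
})

test_that("the full factorial design has 250 trials", {
  d <- enumerate_design()
  expect_equal(nrow(d), 250)
  expect_equal(nrow(unique(d[, c("target", "lighting", "viewpoint")])), 125)
  expect_equal(nrow(enumerate_design(2, 2, 2, 1)), 8)
  expect_error(enumerate_design(n_targets = 6), "<= 5")
  expect_error(enumerate_design(n_reps = 0), ">= 1")
})

test_that("rendered scenes are physically sane", {
  r <- test_scene()
  lum <- r$luminance$values
  expect_true(all(is.finite(lum)))
  expect_true(all(lum >= 0))
  expect_gt(diff(range(lum)), 0)
  expect_s3_class(r$geometry_edges, "edge_map")
  expect_gt(sum(r$geometry_edges$mask), 0)
  expect_named(r$rois, c("whole-step", "corners", "central-edge"))
})

test_that("ROIs nest: corners and central edge partition the whole step", {
  r <- test_scene()
  whole <- r$rois[["whole-step"]]
  parts <- r$rois[["corners"]] | r$rois[["central-edge"]]
  expect_true(all(parts[whole] | !whole[whole]))  # parts subset of whole
  expect_true(all(whole[parts]))
  expect_gt(sum(r$rois[["corners"]]), 0)
  expect_gt(sum(r$rois[["central-edge"]]), 0)
})

test_that("geometry edges land in the whole-step ROI for a frontal view", {
  r <- test_scene()
  hit <- r$geometry_edges$mask & r$rois[["whole-step"]]
  expect_gt(sum(hit), 0)
})

test_that("flat target renders without a step edge in luminance", {
  flat <- render_scene(scene_spec("flat", "overhead", "center",
                                  image_size = 96, ppd = 3))
  step <- test_scene()
  # the flat walkway has no transition band at the target distance
  roi <- flat$rois[["whole-step"]]
  v_flat <- stats::sd(flat$luminance$values[roi])
  v_step <- stats::sd(step$luminance$values[step$rois[["whole-step"]]])
  expect_lt(v_flat, v_step)
  # only the walkway borders remain as geometry; far fewer edge pixels
  expect_lt(sum(flat$geometry_edges$mask & roi),
            sum(step$geometry_edges$mask & step$rois[["whole-step"]]))
})

test_that("different lightings and viewpoints change the rendering", {
  a <- test_scene()$luminance$values
  b <- render_scene(scene_spec("big-step-up", "spotlight-1", "center",
                               image_size = 96, ppd = 3))$luminance$values
  d <- render_scene(scene_spec("big-step-up", "overhead", "pivot-left",
                               image_size = 96, ppd = 3))$luminance$values
  expect_gt(max(abs(a - b)), 1e-6)
  expect_gt(max(abs(a - d)), 1e-6)
})

test_that("rendering is deterministic", {
  s1 <- render_scene(scene_spec("small-step-up", "near-panel", "rotate-up",
                                image_size = 64, ppd = 2))
  s2 <- render_scene(scene_spec("small-step-up", "near-panel", "rotate-up",
                                image_size = 64, ppd = 2))
  expect_identical(s1$luminance$values, s2$luminance$values)
  expect_identical(s1$geometry_edges$mask, s2$geometry_edges$mask)
})

test_that("antialiasing preserves mean luminance and can be disabled", {
  sp <- scene_spec("big-step-up", "overhead", "center",
                   image_size = 64, ppd = 2)
  r1 <- render_scene(sp, supersample = 1)
  r2 <- render_scene(sp, supersample = 2)
  expect_equal(dim(r1$luminance), dim(r2$luminance))
  expect_lt(abs(mean(r1$luminance$values) - mean(r2$luminance$values)) /
              mean(r1$luminance$values), 0.01)
  expect_error(render_scene(sp, supersample = 0), "positive integer")
})

test_that("a camera that cannot see the target errors", {
  expect_error(render_scene(scene_spec("big-step-up", "overhead", "center",
                                       image_size = 16, ppd = 40)),
               "field of view")
})

test_that("scene renders can be written to disk as text-safe artifacts", {
  out <- file.path(tempdir(), "scene_out")
  r <- test_scene()
  write_scene_render(r, out)
  expect_true(file.exists(file.path(out, "scene.pfm")))
  expect_true(file.exists(file.path(out, "scene_geometry.png")))
  expect_true(file.exists(file.path(out, "scene_roi_whole-step.png")))
  expect_true(file.exists(file.path(out, "scene.yaml")))
  unlink(out, recursive = TRUE)
})
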