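test_that("nearest distances agree with brute force on random masks", {
  set.seed(41)
  for (k in 1:10) {
    nr <- sample(6:32, 1); nc <- sample(6:32, 1)
    gm <- matrix(runif(nr * nc) < 0.1, nr, nc)
    bm <- matrix(runif(nr * nc) < 0.07, nr, nc)
    if (!any(gm)) gm[1, 1] <- TRUE
    if (!any(bm)) bm[nr, nc] <- TRUE
    d <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                    edge_map(bm, "luminance"))
    expect_equal(d$distance, unname(brute_force_distances(gm, bm)),
                 tolerance = 1e-12)
  }
})

test_that("distances are infinite when no boundary exists and shapes must match", {
  gm <- matrix(FALSE, 6, 6); gm[3, 3] <- TRUE
  d <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                  edge_map(matrix(FALSE, 6, 6), "luminance"))
  expect_true(is.infinite(d$distance))
  expect_error(
    nearest_boundary_distances(edge_map(gm, "geometry"),
                               edge_map(matrix(FALSE, 5, 6), "luminance")),
    "shape")
})

test_that("score_from_distance implements the linear falloff", {
  ppd <- 6  # d_max = 3 px at the 0.5 degree default
  expect_equal(score_from_distance(0, ppd), 1)
  expect_equal(score_from_distance(1.5, ppd), 0.5)
  expect_equal(score_from_distance(3, ppd), 0)
  expect_equal(score_from_distance(10, ppd), 0)
  expect_equal(score_from_distance(Inf, ppd), 0)
  # resolution independence: same visual-angle separation, same score
  expect_equal(score_from_distance(2, ppd = 6), score_from_distance(4, ppd = 12))
  expect_error(score_from_distance(1, ppd, d_max_deg = 0), "d_max")
  expect_error(score_from_distance(-1, ppd), ">= 0")
})

test_that("scores are non-increasing in distance for both kernels", {
  d <- seq(0, 10, by = 0.25)
  for (k in c("linear", "exponential")) {
    s <- score_from_distance(d, ppd = 6, kernel = k)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("HVS is the mean score over geometry pixels inside the ROI", {
  gm <- matrix(FALSE, 8, 8); gm[4, 2:7] <- TRUE
  bm <- matrix(FALSE, 8, 8); bm[4, 2:4] <- TRUE; bm[6, 7] <- TRUE
  d <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                  edge_map(bm, "luminance"))
  manual <- mean(score_from_distance(d$distance, ppd = 6))
  expect_equal(hazard_visibility_score(d, ppd = 6), manual)
  roi <- matrix(FALSE, 8, 8); roi[, 1:4] <- TRUE
  manual_roi <- mean(score_from_distance(d$distance[d$col <= 4], ppd = 6))
  expect_equal(hazard_visibility_score(d, roi, ppd = 6), manual_roi)
})

test_that("empty ROI is an error, not zero", {
  gm <- matrix(FALSE, 6, 6); gm[2, 2] <- TRUE
  bm <- matrix(FALSE, 6, 6); bm[2, 3] <- TRUE
  d <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                  edge_map(bm, "luminance"))
  roi <- matrix(FALSE, 6, 6); roi[6, 6] <- TRUE
  expect_error(hazard_visibility_score(d, roi, ppd = 6), "empty ROI")
})

test_that("HVS of disjoint ROIs is the pixel-weighted mean of parts", {
  r <- test_scene()
  em <- detect_luminance_boundaries(r$luminance)
  d <- nearest_boundary_distances(r$geometry_edges, em)
  roi_a <- r$rois[["corners"]]
  roi_b <- r$rois[["central-edge"]] & !roi_a  # force strict disjointness
  n_a <- sum(roi_a[cbind(d$row, d$col)])
  n_b <- sum(roi_b[cbind(d$row, d$col)])
  h_a <- hazard_visibility_score(d, roi_a, ppd = r$luminance$ppd)
  h_b <- hazard_visibility_score(d, roi_b, ppd = r$luminance$ppd)
  h_ab <- hazard_visibility_score(d, roi_a | roi_b, ppd = r$luminance$ppd)
  expect_equal(h_ab, (n_a * h_a + n_b * h_b) / (n_a + n_b), tolerance = 1e-12)
})

test_that("dilating the boundary map never decreases any score", {
  set.seed(77)
  gm <- matrix(runif(400) < 0.1, 20, 20)
  bm <- matrix(runif(400) < 0.05, 20, 20)
  if (!any(gm)) gm[1, 1] <- TRUE
  if (!any(bm)) bm[20, 20] <- TRUE
  dil <- bm
  for (dr in -1:1) for (dc in -1:1)
    dil <- dil | hazvis:::shift_mat(bm, dr, dc, fill = FALSE) > 0
  d1 <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                   edge_map(bm, "luminance"))
  d2 <- nearest_boundary_distances(edge_map(gm, "geometry"),
                                   edge_map(dil, "luminance"))
  s1 <- score_from_distance(d1$distance, ppd = 6)
  s2 <- score_from_distance(d2$distance, ppd = 6)
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("perfect pipeline alignment scores near one at high resolution", {
  # at 20 ppd, d_max = 10 px, so rasterization offsets cost little
  r <- render_scene(scene_spec("big-step-up", "overhead", "center",
                               image_size = 320, ppd = 10))
  em <- detect_luminance_boundaries(r$luminance)
  d <- nearest_boundary_distances(r$geometry_edges, em)
  h <- hazard_visibility_score(d, r$rois[["whole-step"]], ppd = 10)
  expect_gt(h, 0.9)
})

test_that("visibility overlay is a valid RGB array with red/green coding", {
  r <- test_scene()
  em <- detect_luminance_boundaries(r$luminance)
  d <- nearest_boundary_distances(r$geometry_edges, em)
  ov <- render_visibility_overlay(r$luminance, d)
  expect_equal(dim(ov), c(dim(r$luminance), 3))
  expect_true(all(ov >= 0 & ov <= 1))
})
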