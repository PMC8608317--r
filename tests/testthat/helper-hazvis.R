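# Shared helpers for the hazvis test suite.

# Three reference observers used across tests: a normally sighted control
# and the two blur-group means from the validation design.
normal_vision <- function() vision_params(acuity = 0, cs = 2.0)
moderate_vision <- function() vision_params(acuity = 1.2, cs = 0.68)
severe_vision <- function() suppressMessages(vision_params(acuity = 1.62))

# A small rendered scene shared by pipeline-level tests (rendering is the
# slow step, so do it once per test file run).
test_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- render_scene(scene_spec("big-step-up", "overhead", "center",
                                        image_size = 96, ppd = 3))
    cache
  }
})

# Brute-force nearest-neighbour distances between two masks, used as an
# oracle for the exact distance transform.
brute_force_distances <- function(geometry_mask, boundary_mask) {
  gi <- which(geometry_mask, arr.ind = TRUE)
  bi <- which(boundary_mask, arr.ind = TRUE)
  if (nrow(gi) == 0L) return(numeric(0))
  if (nrow(bi) == 0L) return(rep(Inf, nrow(gi)))
  apply(gi, 1, function(p)
    sqrt(min((p[1] - bi[, 1])^2 + (p[2] - bi[, 2])^2)))
}

# Brute-force maximum-likelihood logistic fit over a parameter grid,
# used as an oracle for fit_hvs_logistic on tiny datasets.
grid_search_logistic <- function(x, y, a_range, b_range, steps = 3L,
                                 n_grid = 61L) {
  loglik <- function(a, b) {
    p <- stats::plogis(a * x + b)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- c(a = mean(a_range), b = mean(b_range))
  for (s in seq_len(steps)) {
    as <- seq(a_range[1], a_range[2], length.out = n_grid)
    bs <- seq(b_range[1], b_range[2], length.out = n_grid)
    ll <- outer(as, bs, Vectorize(loglik))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(a = as[ij[1]], b = bs[ij[2]])
    da <- diff(a_range) / (n_grid - 1) * 2
    db <- diff(b_range) / (n_grid - 1) * 2
    a_range <- best[1] + c(-da, da)
    b_range <- best[2] + c(-db, db)
  }
  best
}
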