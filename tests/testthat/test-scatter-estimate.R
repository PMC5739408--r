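test_that("single-view estimation recovers slowly varying scatter to ~2%", {
  stack <- cached("est_stack", tiny_stack(spr = 1, noise = FALSE))
  masks <- stack$masks
  for (v in c(2, 6)) {
    est <- estimate_scatter_svsc(stack, masks, v)
    gt <- stack$ground_truth$scatter[[v]]
    rows <- which(masks$eroded[[v]][, 1])
    inner <- min(rows):max(rows)  # sampled axial range
    rel <- abs(est[inner, ] - gt[inner, ]) / mean(gt[inner, ])
    expect_lt(max(rel), 0.02)
  }
})

test_that("zero scatter yields a zero estimate", {
  stack <- tiny_stack(spr = 0)
  est <- estimate_scatter_svsc(stack, stack$masks, 3)
  expect_close(est, 0, tol = 1e-9)
})

test_that("multi-view estimation with one view collapses to single-view", {
  stack <- cached("est_stack", tiny_stack(spr = 1, noise = FALSE))
  sv <- estimate_scatter_svsc(stack, stack$masks, 4)
  mv <- estimate_scatter_mvsc(stack, stack$masks, 4, n_adjacent = 1,
                              max_span_deg = 90)
  expect_identical(sv, mv)
})

test_that("neighbourhoods violating the angular span limit are refused", {
  stack <- cached("est_stack", tiny_stack(spr = 1, noise = FALSE))
  # 8 views over 360 deg: 5 adjacent views span 180 deg
  expect_error(
    estimate_scatter_mvsc(stack, stack$masks, 4, n_adjacent = 5,
                          max_span_deg = 3),
    "span")
  nbr <- neighbor_views(stack$geometry, 4, 3, max_span_deg = 120)
  expect_true(4 %in% nbr && length(nbr) == 3 && all(diff(nbr) == 1))
})

test_that("an end region without samples hurts single-view estimation and
           adjacent views repair it", {
  vol <- tiny_vol(r = 40, hz = 40)
  geom <- tiny_geom(n_views = 20, det = 48, pitch = 3)
  traj <- blocker_trajectory(15, 15, 20, amplitude = 60, period = 8,
                             penumbra_margin = 1, cover = c(-200, 30))
  stack <- acquire(vol, geom, traj, i0 = 1e5, spr = 1, blur_sigma = 40)
  masks <- stack$masks
  err <- function(n_adj) {
    e_end <- e_int <- n_end <- n_int <- 0
    for (v in 1:20) {
      est <- if (n_adj == 1) estimate_scatter_svsc(stack, masks, v) else
        estimate_scatter_mvsc(stack, masks, v, n_adj, max_span_deg = 120)
      gt <- stack$ground_truth$scatter[[v]]
      rows <- which(masks$eroded[[v]][, 1])
      top <- max(rows)
      if (top < geom$det_rows) {
        idx <- (top + 1):geom$det_rows
        e_end <- e_end + sum((est[idx, ] - gt[idx, ])^2)
        n_end <- n_end + length(idx) * geom$det_cols
      }
      idx <- min(rows):top
      e_int <- e_int + sum((est[idx, ] - gt[idx, ])^2)
      n_int <- n_int + length(idx) * geom$det_cols
    }
    c(end = sqrt(e_end / n_end), int = sqrt(e_int / n_int))
  }
  e1 <- err(1); e3 <- err(3); e5 <- err(5)
  expect_gt(e1[["end"]], 2 * e1[["int"]])   # boundary failure present
  expect_lt(e5[["end"]], e3[["end"]])       # monotone improvement
  expect_lt(e3[["end"]], e1[["end"]])
})

test_that("log correction reproduces line integrals when scatter is known", {
  vol <- tiny_vol()
  geom <- tiny_geom(n_views = 4)
  traj <- tiny_traj(geom)
  stack <- acquire(vol, geom, traj, i0 = 1e5, spr = 1, blur_sigma = 40)
  fp <- forward_project(vol, geom, drop = FALSE)
  corr <- correct_and_log(stack, stack$ground_truth$scatter)
  for (v in c(1, 4)) {
    u <- corr$valid[[v]]
    expect_false(any(u & stack$masks$blocked[[v]]))
    expect_close(corr$p_tilde[[v]][u], fp[[v]][u], tol = 1e-9)
    expect_true(all(is.na(corr$p_tilde[[v]][!u])))
  }
})

test_that("over-subtracted pixels clamp at the floor and are counted", {
  vol <- tiny_vol()
  geom <- tiny_geom(n_views = 2)
  traj <- tiny_traj(geom)
  stack <- acquire(vol, geom, traj, i0 = 1e5, spr = 0)
  over <- lapply(1:2, function(v) stack$intensities[[v]] + 1)  # > total
  warns <- capture_warnings(corr <- correct_and_log(stack, over))
  expect_match(warns, "exceeds", all = TRUE)
  expect_true(all(corr$clamped > 0))
  u <- corr$valid[[1]]
  expect_equal(max(corr$p_tilde[[1]][u]), -log(1e-6))
})
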