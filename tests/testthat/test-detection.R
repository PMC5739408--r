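# A controllable synthetic stack for edge detection: flat-edged bands of
# low intensity on a bright background, one band pattern per view.
bands_stack <- function(bands_per_view, n_rows = 60, n_cols = 40,
                        lo = 2e4, hi = 1e5,
                        traj = blocker_trajectory(10, 10, length(bands_per_view),
                                                  amplitude = 0, period = 2)) {
  geom <- scan_geometry(n_views = length(bands_per_view), det_rows = n_rows,
                        det_cols = n_cols, pixel_pitch = 1)
  ints <- lapply(bands_per_view, function(bands) {
    m <- matrix(hi, n_rows, n_cols)
    for (b in bands) m[b[1]:(b[2] - 1), ] <- lo
    m
  })
  manual_stack(ints, geom, traj)
}

test_that("two-point detection recovers flat band edges exactly", {
  truth <- list(list(c(10, 20), c(35, 45)), list(c(5, 15), c(30, 40)))
  stack <- bands_stack(truth)
  em <- detect_edges_two_point(stack, probe_cols = c(5, 35),
                               threshold = 5e4)
  for (v in 1:2) {
    er <- edge_rows(em, v, 20)
    expect_equal(unname(er[, "start"]), vapply(truth[[v]], `[`, 0, 1))
    expect_equal(unname(er[, "end"]), vapply(truth[[v]], `[`, 0, 2))
    # equal rows at both probes: zero slope
    for (b in em$bands[[v]]) expect_equal(b$start[["slope"]], 0)
  }
})

test_that("a perturbed probe point tilts the edge linearly with distance", {
  truth <- list(list(c(20, 30)))
  stack <- bands_stack(truth)
  em <- detect_edges_two_point(stack, probe_cols = c(10, 30),
                               threshold = 5e4,
                               perturb = list(views = 1, delta_rows = 3))
  # line through (10, 20) and (30, 23): error (3/20) * |c - 10|
  for (cc in c(1, 20, 40)) {
    er <- edge_rows(em, 1, cc)
    expect_equal(unname(er[1, "start"]) - 20, 3 / 20 * (cc - 10),
                 tolerance = 1e-12)
  }
})

test_that("mismatched crossing counts raise an error naming the view", {
  # second view has a band only in the right half of the detector
  geom <- scan_geometry(n_views = 1, det_rows = 60, det_cols = 40,
                        pixel_pitch = 1)
  m <- matrix(1e5, 60, 40)
  m[10:20, 1:20] <- 2e4        # band visible at probe column 5 only
  stack <- manual_stack(list(m), geom)
  expect_error(
    detect_edges_two_point(stack, probe_cols = c(5, 35), threshold = 5e4),
    "view 1")
})

test_that("min_envelope is the pointwise minimum with the expected algebra", {
  p1 <- rep(5, 10); p2 <- rep(3, 10)
  expect_equal(min_envelope(list(p1, p2)), rep(3, 10))
  expect_equal(min_envelope(list(p1, p1)), p1)  # idempotent
  set.seed(21)
  ps <- replicate(4, runif(25, 1, 2), simplify = FALSE)
  direct <- min_envelope(ps)
  # iterated pairwise minimum equals the direct minimum; order irrelevant
  iter <- ps[[1]]
  for (k in 2:4) iter <- min_envelope(list(iter, ps[[k]]))
  expect_identical(direct, iter)
  expect_identical(direct, min_envelope(rev(ps)))
  expect_true(all(vapply(ps, function(p) all(direct <= p), logical(1))))
  expect_error(min_envelope(list(1:5, 1:6)), "equal length")
})

test_that("shifted notches across views combine to the union of notches", {
  base <- rep(10, 40)
  mk <- function(at) { p <- base; p[at] <- 2; p }
  profs <- list(mk(5:8), mk(13:16), mk(21:24), mk(29:32))
  env <- min_envelope(profs)
  notch <- c(5:8, 13:16, 21:24, 29:32)
  expect_true(all(env[notch] == 2))
  expect_true(all(env[-notch] == 10))
})

test_that("adaptive thresholding reduces to a global threshold when flat", {
  truth <- rep(list(list(c(10, 20), c(30, 40))), 5)
  stack <- bands_stack(truth, traj = blocker_trajectory(
    10, 10, 5, amplitude = 0, period = 2))
  profs <- lapply(1:5, function(v) axial_profile(stack, v))
  env <- min_envelope(profs)
  em <- adaptive_threshold_edges(env, stack, 3, alpha = 0.5)
  er <- edge_rows(em, 3, 20)
  expect_equal(unname(er[, "start"]), c(10, 30))
  expect_equal(unname(er[, "end"]), c(20, 40))
})

test_that("adaptive thresholding follows a 2:1 intensity fall-off that
           defeats a fixed global threshold", {
  # bright upper half, dim lower half; bands in both halves
  n_rows <- 64
  m <- matrix(0, n_rows, 40)
  level <- ifelse(seq_len(n_rows) <= 32, 1e5, 4e4)
  scat <- ifelse(seq_len(n_rows) <= 32, 2.4e4, 1.2e4)
  for (r in seq_len(n_rows)) m[r, ] <- level[r]
  bands <- list(c(4, 10), c(20, 26), c(36, 42), c(52, 58))
  for (b in bands) m[b[1]:(b[2] - 1), ] <- scat[b[1]]
  geom <- scan_geometry(n_views = 1, det_rows = n_rows, det_cols = 40,
                        pixel_pitch = 1)
  stack <- manual_stack(list(m), geom,
                        blocker_trajectory(6, 10, 1, amplitude = 0,
                                           period = 2))
  # the fixed threshold (profile mean) cannot separate the dim half:
  # it merges its bands with the unblocked rows between them
  prof <- axial_profile(stack, 1)
  fixed <- mean(prof)
  expect_true(nrow(mbscatter:::profile_bands(prof < fixed)) !=
                length(bands))
  # the adaptive rule finds all four
  em <- adaptive_threshold_edges(prof, stack, 1, alpha = 0.5)
  er <- edge_rows(em, 1, 20)
  expect_equal(nrow(er), length(bands))
  expect_close(unname(er[, "start"]), vapply(bands, `[`, 0, 1), tol = 1)
  expect_close(unname(er[, "end"]), vapply(bands, `[`, 0, 2), tol = 1)
})

test_that("small alpha shrinks blocked bands toward the scatter level", {
  stack <- tiny_stack()
  prof <- lapply(1:5, function(v) axial_profile(stack, v))
  env <- min_envelope(prof)
  wide <- adaptive_threshold_edges(env, stack, 3, alpha = 0.5,
                                   refine_cols = FALSE)
  narrow <- adaptive_threshold_edges(env, stack, 3, alpha = 0.15,
                                     refine_cols = FALSE)
  w <- function(em) sum(edge_rows(em, 3, 16)[, "end"] -
                          edge_rows(em, 3, 16)[, "start"])
  expect_lte(w(narrow), w(wide))
})

test_that("degenerate blocker-free profiles are rejected", {
  geom <- scan_geometry(n_views = 1, det_rows = 40, det_cols = 20,
                        pixel_pitch = 1)
  m <- matrix(1e5, 40, 20)
  stack <- manual_stack(list(m), geom)
  expect_error(
    adaptive_threshold_edges(rep(1e5, 40), stack, 1, period_px = 10),
    "degenerate")
})

test_that("edges_to_masks round-trips simulator masks", {
  stack <- tiny_stack()
  geom <- stack$geometry
  em <- detect_edges_adaptive(stack, n_adjacent = 5)
  masks <- edges_to_masks(em, geom, penumbra_margin = 1)
  for (v in c(1, 5, 8)) {
    truth <- mbscatter:::profile_bands(stack$masks$blocked[[v]][, 1])
    det <- mbscatter:::profile_bands(masks$blocked[[v]][, 16])
    expect_equal(nrow(det), nrow(truth))
    expect_true(max(abs(det - truth)) <= stack$trajectory$penumbra_margin + 1)
    expect_true(all(masks$blocked[[v]][masks$eroded[[v]]]))
  }
})
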