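test_that("constant samples give a constant spline everywhere", {
  s <- data.frame(z = seq(-40, 40, by = 4), value = 7.5)
  f <- fit_spline(s, K = 8)
  # partition of unity: constant inside and (clamped) outside the range
  expect_close(predict(f, seq(-80, 80, by = 1)), 7.5, tol = 1e-9)
  expect_close(residuals(f), 0, tol = 1e-9)
})

test_that("a noise-free linear ramp is reproduced exactly", {
  z <- unlist(lapply(c(-30, 0, 25), function(o) o + 0:6))  # 3 views' bands
  s <- data.frame(z = z, value = 2 + 0.5 * z)
  f <- fit_spline(s, K = 6)
  zz <- seq(min(z), max(z), by = 0.5)
  expect_close(predict(f, zz), 2 + 0.5 * zz, tol = 1e-6)
})

test_that("spline weights match an explicit QR least-squares oracle", {
  set.seed(31)
  for (k in 1:25) {
    K <- sample(4:10, 1)
    n <- 3 * K + sample(10:40, 1)
    z <- sort(runif(n, -50, 50))
    y <- sin(z / 12) + rnorm(n, 0, 0.05)
    f <- fit_spline(data.frame(z = z, value = y), K = K)
    h <- diff(range(z)) / (K - 3)
    knots <- min(z) + h * (-3:K)
    B <- splines::splineDesign(knots, z, ord = 4)
    a_qr <- qr.solve(qr(B), y)
    expect_close(coef(f), a_qr, tol = 1e-8 * max(1, max(abs(a_qr))))
  }
})

test_that("fitted weights are a local minimum of the objective", {
  set.seed(55)
  for (k in 1:10) {
    z <- sort(runif(40, -50, 50))
    y <- exp(-z^2 / 800) + rnorm(40, 0, 0.02)
    f <- fit_spline(data.frame(z = z, value = y), K = 7)
    h <- diff(range(z)) / 4
    knots <- min(z) + h * (-3:7)
    B <- splines::splineDesign(knots, z, ord = 4)
    obj <- function(a) sum((y - B %*% a)^2)
    a0 <- coef(f)
    f0 <- obj(a0)
    for (j in seq_along(a0)) for (s in c(-1, 1)) {
      a <- a0
      a[j] <- a[j] * (1 + s * 0.01) + s * 1e-6
      expect_gte(obj(a), f0 - 1e-10)
    }
  }
})

test_that("uncovered knot spans are reported as rank deficiency", {
  s <- data.frame(z = c(seq(0, 10, by = 1), seq(90, 100, by = 1)),
                  value = 1)
  expect_error(fit_spline(s, K = 12), "knot span")
})

test_that("fewer samples than basis functions is an error", {
  s <- data.frame(z = 1:5, value = 1)
  expect_error(fit_spline(s, K = 8), "at least K")
})

test_that("collect_samples pools eroded blocked pixels across views", {
  stack <- tiny_stack()
  masks <- stack$masks
  one <- collect_samples(stack, masks, views = 4, col = 16)
  expect_true(all(masks$eroded[[4]][cbind(one$row, 16)]))
  # five views with distinct offsets multiply the sample count ~5x
  nbr <- 2:6
  expect_true(length(unique(stack$trajectory$offset_per_view[nbr])) == 5)
  five <- collect_samples(stack, masks, views = nbr, col = 16)
  expect_gte(nrow(five), 4.5 * nrow(one))
  # identical offsets: duplicated positions are retained
  t2 <- blocker_trajectory(16, 16, stack$geometry$n_views, amplitude = 0,
                           period = 2, penumbra_margin = 1)
  m2 <- build_masks(t2, stack$geometry)
  dup <- collect_samples(stack, m2, views = c(1, 2), col = 16)
  expect_equal(nrow(dup), 2 * nrow(collect_samples(stack, m2, 1, 16)))
  expect_true(any(duplicated(dup$z)))
})

test_that("views without eroded blocked pixels are rejected", {
  stack <- tiny_stack()
  masks <- stack$masks
  masks$eroded[[2]][] <- FALSE
  expect_error(collect_samples(stack, masks, views = 1:3, col = 5),
               "view 2")
})
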