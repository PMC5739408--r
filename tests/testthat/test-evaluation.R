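test_that("HU conversion maps water to 0, air to -1000 and is invertible", {
  expect_equal(to_hu(array(0.02, c(2, 2, 2)), 0.02),
               array(0, c(2, 2, 2)))
  expect_equal(unique(as.numeric(to_hu(array(0, c(2, 2, 2)), 0.02))),
               -1000)
  expect_equal(unique(as.numeric(to_hu(array(0.04, c(2, 2, 2)), 0.02))),
               1000)
  set.seed(3)
  mu <- array(runif(27, 0, 0.05), c(3, 3, 3))
  expect_close(from_hu(to_hu(mu, 0.019), 0.019), mu, tol = 1e-12)
  expect_error(to_hu(mu, 0), "positive")
})

test_that("ROI statistics match a brute-force voxel loop", {
  vol <- attenuation_volume(array(0.02, c(16, 16, 16)), 4)
  set.seed(8)
  vol$values <- vol$values + array(runif(16^3, 0, 0.01), c(16, 16, 16))
  roi <- roi_spec("probe", "cylinder", center = c(5, -4, 0), radius = 12,
                  half_size = c(12, 12, 10))
  st <- roi_stats(vol, roi)
  # explicit enumeration oracle
  vals <- c()
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    x <- vol$origin[1] + (i - 0.5) * 4 - 5
    y <- vol$origin[2] + (j - 0.5) * 4 + 4
    z <- vol$origin[3] + (k - 0.5) * 4
    if (x^2 + y^2 <= 144 && abs(z) <= 10)
      vals <- c(vals, vol$values[i, j, k])
  }
  expect_equal(st[["n"]], length(vals))
  expect_equal(st[["mean"]], mean(vals), tolerance = 1e-12)
  expect_equal(st[["std"]], sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)
})

test_that("uniform and two-voxel ROIs give textbook statistics", {
  vol <- attenuation_volume(array(0.03, c(8, 8, 8)), 4)
  roi <- roi_spec("all", "box", c(0, 0, 0), half_size = c(16, 16, 16))
  st <- roi_stats(vol, roi)
  expect_equal(st[["mean"]], 0.03)
  expect_equal(st[["std"]], 0)
  vol2 <- attenuation_volume(array(0, c(2, 1, 1)), 4, origin = c(-4, -2, -2))
  vol2$values[2, 1, 1] <- 2
  roi2 <- roi_spec("pair", "box", c(0, 0, 0), half_size = c(8, 8, 8))
  st2 <- roi_stats(vol2, roi2)
  expect_equal(st2[["mean"]], 1)
  expect_equal(st2[["std"]], 1)
})

test_that("ROI RMSE is symmetric and matches hand arithmetic", {
  a <- attenuation_volume(array(0, c(2, 1, 1)), 4, origin = c(-4, -2, -2))
  b <- a
  a$values[] <- c(1, 2)
  b$values[] <- c(2, 4)
  roi <- roi_spec("pair", "box", c(0, 0, 0), half_size = c(8, 8, 8))
  expect_equal(roi_rmse(a, b, roi), sqrt((1 + 4) / 2))
  expect_equal(roi_rmse(a, b, roi), roi_rmse(b, a, roi))
  expect_equal(roi_rmse(a, a, roi), 0)
  # constant offset d gives |d|
  c2 <- a; c2$values <- a$values + 3
  expect_equal(roi_rmse(a, c2, roi), 3)
  # RMSE^2 >= squared mean error (random check)
  set.seed(12)
  d <- a; d$values <- a$values + rnorm(2)
  expect_gte(roi_rmse(a, d, roi)^2,
             mean(a$values - d$values)^2 - 1e-12)
})

test_that("method comparison tabulates Mean, STD, RMSE per ROI", {
  vol <- tiny_vol()
  rois <- list(roi_spec("core", "cylinder", c(0, 0, 0), radius = 20,
                        half_size = c(20, 20, 20)))
  rep <- compare_methods(vol, list(perfect = vol), rois, mu_water = 0.02)
  expect_equal(names(rep), c("roi", "method", "mean", "std", "rmse"))
  expect_equal(rep$rmse[rep$method == "perfect"], 0)
  expect_equal(rep$mean[rep$method == "perfect"], 0)  # water HU
  expect_error(compare_methods(vol, list(vol), rois), "named")
})
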