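test_that("top/bottom statistics match a sort-based oracle", {
  hm <- hm_from_heights(as.numeric(1:20))
  rec <- top_bottom_deformation(hm, k = 5)
  expect_equal(rec$top, 18)
  expect_equal(rec$bottom, 3)
  expect_equal(rec$deformation, 15)

  expect_equal(top_bottom_deformation(hm_from_heights(rep(7, 9)))$deformation,
               0)

  set.seed(2)
  for (rep in 1:10) {
    h <- rnorm(150, 20, 6)
    h[sample(150, 30)] <- NA
    hm <- hm_from_heights(h)
    k <- sample(1:10, 1)
    v <- sort(h[!is.na(h)], decreasing = TRUE)
    rec <- top_bottom_deformation(hm, k)
    expect_identical(rec$top, mean(v[1:k]))
    expect_identical(rec$bottom, mean(rev(v)[1:k]))
    expect_equal(rec$skewness, skew_oracle(h[!is.na(h)]), tolerance = 1e-12)
  }
  expect_error(top_bottom_deformation(hm_from_heights(c(1, 2, NA)), k = 5),
               "2 valid cells but k = 5")
})

test_that("the internal skewness matches e1071's bias-corrected estimator", {
  set.seed(4)
  x <- rexp(60)
  expect_equal(top_bottom_deformation(hm_from_heights(x), 5)$skewness,
               e1071::skewness(x, type = 2), tolerance = 1e-12)
})

test_that("deformation shrinks as k grows and ignores uniform shifts", {
  set.seed(3)
  h <- rnorm(300, 0, 5)
  hm <- hm_from_heights(h)
  defs <- vapply(1:20, function(k) {
    top_bottom_deformation(hm, k)$deformation
  }, numeric(1))
  expect_true(all(diff(defs) <= 1e-12))

  shifted <- hm_from_heights(h + 100)
  expect_equal(top_bottom_deformation(shifted, 5)$deformation,
               top_bottom_deformation(hm, 5)$deformation, tolerance = 1e-9)
})

test_that("cells classify into hills/valleys by deviation thresholds", {
  h <- c(11, 20, 29, 15, 25)  # mean 20, deviations -9, 0, 9, -5, 5
  cls <- classify_cells(hm_from_heights(h))
  expect_equal(cls$side, c("valley", "valley", "hill", "valley", "hill"))
  expect_equal(cls$category, c("I", "III", "I", "II", "II"))
  expect_equal(cls$zero_dev, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("classification tallies match a per-cell enumeration oracle", {
  set.seed(5)
  for (rep in 1:20) {
    h <- rnorm(120, 15, sample(3:8, 1))
    h[sample(120, 20)] <- NA
    hm <- hm_from_heights(h)
    cls <- classify_cells(hm)
    v <- h[!is.na(h)]
    dev <- v - mean(v)
    oracle <- table(
      side = ifelse(dev > 0, "hill", "valley"),
      cat = ifelse(abs(dev) >= 8, "I", ifelse(abs(dev) >= 4, "II", "III"))
    )
    expect_equal(table(side = cls$side, cat = cls$category), oracle)
    expect_equal(sum(cls$side == "hill") + sum(cls$side == "valley"),
                 length(v))
  }
})

test_that("category fractions reflect the Gaussian tail closed form", {
  set.seed(6)
  sigma <- 5
  h <- rnorm(4608 * 30, 20, sigma)
  hm <- hm_from_heights(h, nx = 64 * 30, ny = 72)
  cls <- classify_cells(hm)
  p1 <- mean(cls$category == "I")
  expected <- 2 * pnorm(-8 / sigma)
  mc_se <- sqrt(expected * (1 - expected) / length(h))
  expect_lt(abs(p1 - expected), 4 * mc_se + 1e-4)
})

test_that("cumulative distributions pool cell-frame observations", {
  one <- tibble::tibble(
    frame = 1L, side = "valley",
    category = rep("III", 4), zero_dev = FALSE
  )
  d1 <- cumulative_category_distribution(one)
  expect_equal(d1$fraction[d1$side == "valley"], c(0, 0, 1))

  two <- tibble::tibble(
    frame = rep(1:2, each = 4), side = "hill",
    category = c("I", "II", "III", "III", "III", "III", "III", "III"),
    zero_dev = FALSE
  )
  d2 <- cumulative_category_distribution(two)
  expect_equal(d2$fraction[d2$side == "hill"], c(0.125, 0.125, 0.75))

  # with constant per-frame cell counts, pooling equals frame-averaging
  d3 <- cumulative_category_distribution(two, method = "per_frame")
  expect_equal(d3$fraction[d3$side == "hill"], c(0.125, 0.125, 0.75))
})

test_that("deformation series summarize with mean and standard error", {
  g <- flat_gen()
  up <- height_map_series(g$trajectory, "upper")
  ds <- deformation_series(up, k = 5)
  expect_equal(nrow(ds), 3)
  expect_true(all(ds$deformation == 0))
  s <- glance(ds)
  expect_equal(s$mean_deformation, 0)
  expect_equal(s$se_deformation, 0)
})

test_that("the deformation statistic is insensitive to the choice of k", {
  g <- cached("noisy_mode", generate_bilayer(synthetic_params(
    head_density = 0.2,
    modes = list(surface_mode(5, c(2 * pi / 80, 0), phase = 0.4,
                              angular_speed = 2)),
    noise_sigma = 0.5, drift_upper_x = 0, drift_lower_x = 0,
    protein = NULL, bump = NULL, n_frames = 8, seed = 31
  )))
  up <- height_map_series(g$trajectory, "upper")
  means <- vapply(c(3, 5, 10), function(k) {
    glance(deformation_series(up, k = k))$mean_deformation
  }, numeric(1))
  expect_lt((max(means) - min(means)) / mean(means), 0.1)
})

test_that("skewness trends fit exact lines and flag stationarity", {
  recs <- tibble::tibble(time = seq(0, 2, by = 0.1),
                         skewness = 0.3)
  expect_equal(skewness_trend(recs)$slope, 0, tolerance = 1e-12)

  recs2 <- tibble::tibble(time = seq(0, 2, by = 0.1))
  recs2$skewness <- 0.1 * recs2$time
  fit <- skewness_trend(recs2)
  expect_equal(fit$slope, 0.1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)

  g <- cached("stationary", generate_bilayer(params_stationary()))
  ds <- deformation_series(height_map_series(g$trajectory, "upper"))
  gl <- glance(skewness_trend(ds))
  expect_lt(abs(gl$slope), 2 * gl$slope_se)

  expect_error(skewness_trend(recs2[1:2, ]), "at least 3")
})
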