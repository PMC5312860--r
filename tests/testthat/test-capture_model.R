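heights <- c(1.0, 1.5, 2.0, 3.0, 4.0)
translations <- c(0, 0.5, 1.0, 1.5, 2.0)

noiseless_height <- function(a, b) data.frame(
  height = heights, probability = a - b * heights)
noiseless_translation <- function(a, b, s, h = 3) data.frame(
  translation = translations,
  probability = a - b * h - s * translations)

test_that("model evaluation is the raw linear form, unclamped", {
  up <- capture_model(72, 16.5, orientation = "up")
  down <- capture_model(93, 20.5, orientation = "down")
  expect_equal(as.numeric(predict(up, 0, 0)), 72)
  expect_equal(as.numeric(predict(down, 0, 0)), 93)
  full_down <- capture_model(93, 20.5, 6.2)
  expect_equal(as.numeric(predict(full_down, 1, 1)), 66.3)
  # values outside [0, 100] are returned raw but flagged
  far <- predict(down, 10, 0)
  expect_lt(as.numeric(far), 0)
  expect_true(attr(far, "out_of_range"))
  expect_error(predict(up, -1, 0), "non-negative")
  expect_error(predict(up, 1, -1), "non-negative")
})

test_that("prediction is affine in both covariates", {
  m <- capture_model(93, 20.5, 6.2)
  for (h in c(0, 1, 2.5)) for (t in c(0, 0.7)) {
    expect_equal(as.numeric(predict(m, h, t) - predict(m, h, t + 1)), 6.2)
    expect_equal(as.numeric(predict(m, h, t) - predict(m, h + 1, t)), 20.5)
  }
})

test_that("noiseless linear data are recovered to machine precision", {
  for (cf in list(c(72, 16.5), c(93, 20.5))) {
    f <- fit_height_model(noiseless_height(cf[1], cf[2]))
    expect_equal(f$intercept, cf[1], tolerance = 1e-10)
    expect_equal(f$height_slope, cf[2], tolerance = 1e-10)
    expect_equal(f$translation_slope, 0)
  }
  # constant data give a flat line
  flat <- fit_height_model(data.frame(height = heights, probability = 50))
  expect_equal(flat$intercept, 50, tolerance = 1e-10)
  expect_equal(flat$height_slope, 0, tolerance = 1e-10)
  # two points determine the line exactly
  two <- fit_height_model(data.frame(height = c(0, 1),
                                     probability = c(72, 55.5)))
  expect_equal(c(two$intercept, two$height_slope), c(72, 16.5),
               tolerance = 1e-10)
  expect_error(fit_height_model(data.frame(height = c(2, 2),
                                           probability = c(10, 20))),
               "distinct")
})

test_that("height fits agree with a brute-force grid-search oracle", {
  set.seed(17)
  for (i in 1:5) {
    pts <- data.frame(height = heights,
                      probability = runif(5, 20, 90))
    f <- fit_height_model(pts)
    # coarse grid search over (intercept, slope)
    a_grid <- seq(0, 120, by = 0.5)
    b_grid <- seq(-30, 40, by = 0.5)
    sse <- outer(a_grid, b_grid, function(a, b)
      vapply(seq_along(a), function(k)
        sum((pts$probability - (a[k] - b[k] * pts$height))^2), numeric(1)))
    sse_fit <- sum((pts$probability -
                      (f$intercept - f$height_slope * pts$height))^2)
    # the closed-form fit can never do worse than any grid point
    expect_lte(sse_fit, min(sse) + 1e-9)
    # and the best grid point's line lies close to the fitted one
    best <- arrayInd(which.min(sse), dim(sse))
    pred_fit <- f$intercept - f$height_slope * heights
    pred_grid <- a_grid[best[1]] - b_grid[best[2]] * heights
    expect_lt(max(abs(pred_fit - pred_grid)), 1.5)
  }
})

test_that("height-effect removal anchors the series by a constant shift", {
  hm <- fit_height_model(noiseless_height(72, 16.5))
  # a series whose anchor already matches the prediction is unchanged
  tp <- noiseless_translation(72, 16.5, 2.3)
  adj <- remove_height_effect(tp, hm, 3)
  expect_equal(adj$probability, tp$probability, tolerance = 1e-9)
  expect_equal(attr(adj, "shift"), 0, tolerance = 1e-9)
  # prediction 31.5, observed anchor 35: everything shifts by -3.5
  hm2 <- capture_model(93, 20.5)
  tp2 <- data.frame(translation = c(0, 1, 2), probability = c(35, 30, 25))
  adj2 <- remove_height_effect(tp2, hm2, 3)
  expect_equal(attr(adj2, "shift"), -3.5)
  expect_equal(adj2$probability, c(31.5, 26.5, 21.5))
  expect_equal(adj2$probability[1], as.numeric(predict(hm2, 3, 0)))
  # no zero-translation anchor: undefined
  expect_error(remove_height_effect(
    data.frame(translation = c(1, 2), probability = c(1, 2)), hm2, 3),
    "anchor")
})

test_that("combined fits recover all coefficients on noiseless input", {
  for (cf in list(c(72, 16.5, 2.3), c(93, 20.5, 6.2))) {
    f <- fit_combined_model(noiseless_height(cf[1], cf[2]),
                            noiseless_translation(cf[1], cf[2], cf[3]))
    expect_equal(f$intercept, cf[1], tolerance = 1e-9)
    expect_equal(f$height_slope, cf[2], tolerance = 1e-9)
    expect_equal(f$translation_slope, cf[3], tolerance = 1e-9)
  }
  # zero translation effect
  f0 <- fit_combined_model(noiseless_height(93, 20.5),
                           noiseless_translation(93, 20.5, 0))
  expect_equal(f0$translation_slope, 0, tolerance = 1e-12)
})

test_that("coefficient bias shrinks with replicates on Bernoulli data", {
  truth <- capture_model(93, 20.5, 6.2, orientation = "down")
  run_recovery <- function(reps, seed) {
    grid <- rbind(
      expand.grid(height = heights, translation = 0,
                  replicate = seq_len(reps)),
      expand.grid(height = 3, translation = translations[-1],
                  replicate = seq_len(reps)))
    grid$orientation <- "down"
    out <- sample_outcomes(truth, grid, seed = seed)
    tab <- probability_table(out)
    fit_combined_model(height_series(tab, "down"),
                       translation_series(tab, "down"))
  }
  small <- run_recovery(20, 1)
  big <- run_recovery(2000, 2)
  err <- function(f) abs(c(f$intercept - 93, f$height_slope - 20.5,
                           f$translation_slope - 6.2))
  # the large-sample fit is close; the small-sample fit need not be
  expect_true(all(err(big) < c(3, 1.5, 1.5)))
  expect_true(all(err(big) <= err(small) + c(3, 1.5, 1.5)))
})

test_that("propagated coefficient SEs match a Monte-Carlo replication", {
  truth <- capture_model(72, 16.5, 2.3, orientation = "up")
  reps <- 200
  one <- function(seed) {
    grid <- rbind(
      expand.grid(height = heights, translation = 0,
                  replicate = seq_len(reps)),
      expand.grid(height = 3, translation = translations[-1],
                  replicate = seq_len(reps)))
    grid$orientation <- "up"
    tab <- probability_table(sample_outcomes(truth, grid, seed = seed))
    fit_combined_model(height_series(tab, "up"),
                       translation_series(tab, "up"))
  }
  fits <- lapply(1:60, one)
  slopes <- vapply(fits, function(f) f$translation_slope, numeric(1))
  hslopes <- vapply(fits, function(f) f$height_slope, numeric(1))
  prop <- fits[[1]]$metadata$coef_se
  # analytic propagation should match the empirical spread within ~40%
  expect_lt(abs(sd(slopes) - prop[["translation_slope"]]),
            0.4 * sd(slopes))
  expect_lt(abs(sd(hslopes) - prop[["height_slope"]]), 0.4 * sd(hslopes))
})

test_that("free-intercept translation fit matches the anchored one on noiseless data", {
  hp <- noiseless_height(93, 20.5)
  tp <- noiseless_translation(93, 20.5, 6.2)
  a <- fit_combined_model(hp, tp, anchored = TRUE)
  b <- fit_combined_model(hp, tp, anchored = FALSE)
  expect_equal(b$translation_slope, a$translation_slope, tolerance = 1e-9)
  # with a biased anchor point the two modes disagree, free-intercept
  # following the interior points
  tp2 <- tp
  tp2$probability[tp2$translation == 0] <- tp2$probability[1] + 10
  expect_gt(abs(fit_combined_model(hp, tp2, anchored = TRUE)$translation_slope -
                  fit_combined_model(hp, tp2, anchored = FALSE)$translation_slope),
            0.5)
})
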