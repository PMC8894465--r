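test_that("window counting matches the closed form", {
  expect_equal(window_count(4800, 42, 1), 4759)
  expect_equal(window_count(10, 10, 1), 1)
  expect_equal(window_count(100, 30, 10), 8)
  expect_error(window_count(10, 11, 1), "longer")
})

test_that("sliding windows recover exact correlations", {
  x <- matrix(rnorm(200), 1, 200)
  panel <- time_series_panel(rbind(x, x, -x), 0.72)
  dc <- sliding_window_fc(panel, window_seconds = 30, step_seconds = 7.2)
  expect_equal(dc$window_samples, 42)  # 30 s at 0.72 s sampling
  expect_equal(dim(dc$tensor)[3], window_count(200, 42, 10))
  expect_true(all(abs(dc$tensor[1, 2, ] - 1) < 1e-12))
  expect_true(all(abs(dc$tensor[1, 3, ] + 1) < 1e-12))
  expect_true(all(apply(dc$tensor, 3, isSymmetric)))
  # a zero-variance node yields 0 correlations, with a message
  flat <- time_series_panel(rbind(x, matrix(1, 1, 200)), 0.72)
  expect_message(dcf <- sliding_window_fc(flat, 30, 7.2), "zero-variance")
  expect_true(all(dcf$tensor[1, 2, ] == 0))
})

test_that("the paper-scale window geometry yields 4759 slices", {
  panel <- time_series_panel(matrix(rnorm(3 * 4800), 3, 4800), 0.72)
  dc <- sliding_window_fc(panel, window_seconds = 30)
  expect_equal(dim(dc$tensor)[3], 4759)
})

test_that("static community structure gives constant matched labels", {
  p <- generate_switch_panel(30, 400, 0.72, integer(0), 3, noise_sd = 0.2,
                             seed = 1)
  dc <- sliding_window_fc(p, 30, step_seconds = 0.72 * 42)
  labs <- dynamic_communities(dc, seed = 2)
  expect_true(all(labs == labs[, 1]))
  fl <- flexibility(labs)
  expect_equal(fl$mean_flexibility, 0)
})

test_that("a planted mid-series switch registers only near the transition", {
  # switch at sample 210 = boundary of non-overlapping 42-sample windows
  p <- generate_switch_panel(30, 420, 0.72, 210, 3, noise_sd = 0.2, seed = 3)
  dc <- sliding_window_fc(p, 30, step_seconds = 0.72 * 42)
  labs <- dynamic_communities(dc, seed = 4)
  changes <- colSums(labs[, -1, drop = FALSE] != labs[, -ncol(labs),
                                                      drop = FALSE])
  expect_gt(changes[5], 0)            # windows 5|6 straddle the switch
  expect_true(all(changes[-5] == 0))  # quiet elsewhere
})

test_that("flexibility limits and label-permutation invariance hold", {
  const <- matrix(1, 10, 6)
  expect_equal(flexibility(const)$mean_flexibility, 0)
  alt <- matrix(rep(c(1, 2), length.out = 6), 10, 6, byrow = TRUE)
  expect_equal(flexibility(alt)$mean_flexibility, 1)
  labs <- matrix(sample(1:3, 50, replace = TRUE), 10, 5)
  perm <- c(3, 1, 2)
  expect_equal(flexibility(labs)$per_node_flexibility,
               flexibility(matrix(perm[labs], 10, 5))$per_node_flexibility)
  # one change in four transitions
  expect_equal(flexibility(matrix(c(1, 1, 2, 2, 2), 1, 5))$mean_flexibility,
               0.25)
  expect_error(flexibility(matrix(1, 5, 1)), "at least 2")
})

test_that("estimated flexibility increases with the planted switch rate", {
  rates <- c(0, 2, 4, 6, 8)
  flex <- matrix(NA_real_, length(rates), 6)
  for (i in seq_along(rates)) {
    for (s in 1:6) {
      st <- withr::with_seed(5000 + 100 * i + s, {
        if (rates[i] == 0) integer(0) else sort(sample.int(899, rates[i]))
      })
      p <- generate_switch_panel(30, 900, 0.72, st, 3, noise_sd = 0.6,
                                 seed = 6000 + 100 * i + s)
      flex[i, s] <- panel_flexibility(p, 30, 15.12,
                                      seed = 7000 + i)$mean_flexibility
    }
  }
  rho <- cor(rep(rates, 6), as.vector(flex), method = "spearman")
  expect_gt(rho, 0.9)
})
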