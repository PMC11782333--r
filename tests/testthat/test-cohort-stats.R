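test_that("median split of the published fixture reproduces the subgroup stats", {
  t1 <- table1_fixture()
  sc <- median_split_comparison(t1)
  expect_equal(sc$threshold, 18.33, tolerance = 1e-9)
  expect_equal(sc$high$n, 6)
  expect_equal(sc$low$n, 6)
  expect_equal(sc$high$median, 0.67, tolerance = 1e-9)
  expect_equal(sc$high$q1, 0.515, tolerance = 1e-9)   # prints as 0.51
  expect_equal(sc$high$q3, 0.87, tolerance = 1e-9)
  expect_equal(sc$low$median, 0.32, tolerance = 1e-9)
  expect_equal(sc$low$q1, 0.25, tolerance = 1e-9)
  expect_equal(sc$low$q3, 0.3375, tolerance = 1e-9)   # prints as 0.34
  expect_gt(sc$high$median, sc$low$median)
  expect_lt(sc$p_value, 0.05)
  # invariant to record ordering
  set.seed(51)
  sc2 <- median_split_comparison(t1[sample(nrow(t1)), ])
  expect_equal(sc2$threshold, sc$threshold)
  expect_equal(sc2$high$median, sc$high$median)
  expect_equal(sc2$p_value, sc$p_value)
})

test_that("median split handles hand-checkable and degenerate cases", {
  r4 <- data.frame(hlpr = c(0.1, 0.2, 0.3, 0.4),
                   osi_area_percent = c(1, 2, 3, 4))
  sc <- median_split_comparison(r4)
  expect_equal(sc$threshold, 2.5)
  expect_equal(sort(sc$high$records$hlpr), c(0.3, 0.4))
  expect_equal(sort(sc$low$records$hlpr), c(0.1, 0.2))
  # all records equal: the high group is empty
  same <- data.frame(hlpr = 1:4 / 10, osi_area_percent = rep(7, 4))
  expect_error(median_split_comparison(same), "empty")
  expect_error(median_split_comparison(r4[1:3, ]), "at least 4")
})

test_that("noiseless random-intercept data is recovered exactly", {
  x <- rep(seq(100, 600, by = 100), 3)
  g <- rep(c("A", "B", "C"), each = 6)
  offs <- c(A = -1, B = 0, C = 1)[g]
  y <- 10 + 2 * x + offs
  fit <- fit_random_intercept_model(y, x, g, n_boot = 50, seed = 99)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_lt(fit$residual_sd, 1e-4)
  expect_true(fit$ci_low <= fit$slope && fit$slope <= fit$ci_high)
})

test_that("zero between-patient variance collapses to the pooled OLS slope", {
  set.seed(52)
  x <- runif(40, 0, 10)
  g <- rep(letters[1:4], each = 10)
  y <- 3 + 0.5 * x + rnorm(40, 0, 0.3)   # no patient offsets at all
  fit <- fit_random_intercept_model(y, x, g, n_boot = 20, seed = 1)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_equal(fit$slope, ols, tolerance = 1e-6)
})

test_that("one observation per patient degenerates to closed-form OLS", {
  set.seed(53)
  x <- runif(12); y <- 1 + 2 * x + rnorm(12, 0, 0.1)
  g <- paste0("p", 1:12)
  fit <- fit_random_intercept_model(y, x, g, n_boot = 30, seed = 2)
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, beta_hat, tolerance = 1e-9)
  expect_equal(fit$patient_intercept_sd, 0)
})

test_that("the bootstrap is reproducible for a fixed seed", {
  co <- gen_cohort(seed = 7)
  f1 <- fit_random_intercept_model(co$records$max_peak_amplitude,
                                   co$records$brachial_bfv_ml_min,
                                   co$records$patient_id,
                                   n_boot = 40, seed = 123)
  f2 <- fit_random_intercept_model(co$records$max_peak_amplitude,
                                   co$records$brachial_bfv_ml_min,
                                   co$records$patient_id,
                                   n_boot = 40, seed = 123)
  expect_identical(f1$boot_slopes, f2$boot_slopes)
  expect_identical(c(f1$ci_low, f1$ci_high), c(f2$ci_low, f2$ci_high))
})

test_that("consecutive-visit deltas are later-minus-earlier in schedule order", {
  rec <- data.frame(patient_id = c("P1", "P1"), visit = c("3d", "3w"),
                    hlpr = c(0.3, 0.2),
                    brachial_bfv_ml_min = c(400, 700))
  d <- longitudinal_deltas(rec)
  expect_equal(d$delta_bfv, 300)
  expect_equal(d$delta_hlpr, -0.1)
  # schedule order wins over row order
  d2 <- longitudinal_deltas(rec[2:1, ])
  expect_equal(d2$delta_bfv, 300)
  # a visit missing HLPR drops the pairs that use it
  rec3 <- data.frame(patient_id = "P1", visit = c("3d", "3w", "3m"),
                     hlpr = c(0.3, NA, 0.5),
                     brachial_bfv_ml_min = c(400, 700, 600))
  d3 <- longitudinal_deltas(rec3)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$visit_from, "3d"); expect_equal(d3$visit_to, "3m")
  # single-visit patients contribute nothing
  expect_equal(nrow(longitudinal_deltas(rec[1, ])), 0)
})

test_that("published P1 HLPR trajectory gives deltas 0.03 and 0.25", {
  t1 <- table1_fixture()
  p1 <- t1[t1$patient_id == "P1", ]
  p1$brachial_bfv_ml_min <- 0          # delta machinery needs both columns
  d <- longitudinal_deltas(p1)
  expect_equal(d$delta_hlpr, c(0.03, 0.25), tolerance = 1e-9)
})

test_that("operator agreement matches closed-form Pearson and Bland-Altman", {
  x <- c(0.2, 0.4, 0.6, 0.8); y <- c(0.25, 0.38, 0.66, 0.75)
  res <- operator_agreement(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(res$mean_difference, mean(x - y))
  expect_equal(res$loa_high - res$loa_low, 2 * 1.96 * sd(x - y))
  # identical series: perfect agreement, degenerate limits
  res_id <- operator_agreement(x, x + 0)
  expect_equal(res_id$pearson_r, 1)
  expect_equal(res_id$mean_difference, 0)
  expect_equal(res_id$loa_low, 0); expect_equal(res_id$loa_high, 0)
  expect_equal(operator_agreement(x, -x)$pearson_r, -1)
  expect_error(operator_agreement(x, rep(1, 4)), "zero variance")
  expect_error(operator_agreement(x[1:2], y[1:2]), "at least 3")
})

test_that("Bland-Altman limits hold ~95% of large normal samples", {
  set.seed(54)
  x <- rnorm(4000); y <- x + rnorm(4000, 0.1, 0.5)
  res <- operator_agreement(x, y)
  inside <- mean(res$differences >= res$loa_low &
                   res$differences <= res$loa_high)
  expect_gt(inside, 0.94); expect_lt(inside, 0.96)
})
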