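make_flows <- function(f15, f13, f11, site_id = "S01") {
  data.frame(site_id = site_id, hour = c(15, 13, 11),
             veh_per_h = c(f15, f13, f11))
}

test_that("traffic_x sums squared log10 flows over three hours", {
  expect_equal(traffic_x(make_flows(100, 100, 100))$x, 12)
  expect_equal(traffic_x(make_flows(1000, 1000, 1000))$x, 27)
  # half-decade flows: 3.5^2 + 3^2 + 2.5^2 = 27.5 exactly at powers of 10
  expect_equal(traffic_x(make_flows(10^3.5, 10^3, 10^2.5))$x, 27.5)
  expect_equal(traffic_x(make_flows(3162, 1000, 316))$x, 27.5,
               tolerance = 1e-2)
  # flooring and errors
  expect_warning(x0 <- traffic_x(make_flows(0.2, 100, 100)), "floored")
  expect_equal(x0$x, 8)
  expect_error(traffic_x(make_flows(-1, 100, 100)), "negative")
  # explicit hours select different flows
  fl <- data.frame(site_id = "S01", hour = 0:23, veh_per_h = 10^(0:23 / 10))
  x <- traffic_x(fl, hours = c(10, 20, 23))
  expect_equal(x$x, 1^2 + 2^2 + 2.3^2)
})

test_that("split_train_test respects ratio, classes and determinism", {
  sites <- data.frame(site_id = sprintf("S%02d", 1:90),
                      cluster = rep(1:2, c(34, 56)),
                      x = runif(90))
  sp <- split_train_test(sites, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 63)
  expect_equal(nrow(sp$test), 27)
  expect_setequal(c(sp$train$site_id, sp$test$site_id), sites$site_id)
  expect_gte(min(table(sp$train$cluster)), 1)
  # determinism
  sp2 <- split_train_test(sites, 0.7, seed = 4)
  expect_identical(sp$train$site_id, sp2$train$site_id)
  # 4 sites at ratio 0.5 -> 2/2
  s4 <- data.frame(cluster = c(1, 1, 2, 2))
  sp4 <- split_train_test(s4, 0.5, seed = 1)
  expect_equal(nrow(sp4$train), 2)
  expect_equal(nrow(sp4$test), 2)
})

test_that("fit_logistic recovers generating coefficients (seeded)", {
  # simulate from the exponent convention P = 1/(1 + exp(-6.84 + 1.26 x))
  with_seed(2024, {
    n <- 5000
    x <- runif(n, 0, 11)
    p <- 1 / (1 + exp(-6.84 + 1.26 * x))
    y <- rbinom(n, 1, p)
    fit <- fit_logistic(x, y)
    expect_true(fit$converged)
    expect_false(fit$separation)
    expect_lt(abs(fit$intercept_term - -6.84), 0.2)
    expect_lt(abs(fit$slope_term - 1.26), 0.2)
    # independent oracle: glm's IRLS on the same data
    ref <- glm(y ~ x, family = binomial())
    expect_equal(-fit$intercept_term, unname(coef(ref)[1]),
                 tolerance = 1e-6)
    expect_equal(-fit$slope_term, unname(coef(ref)[2]), tolerance = 1e-6)
  })
})

test_that("fit_logistic symmetry, replication invariance, separation", {
  # balanced symmetric classes around x = 5 -> threshold ~ 5
  x <- c(3, 3.5, 4, 4.5, 5.5, 6, 6.5, 7)
  y <- c(2, 2, 2, 2, 1, 1, 1, 1)   # cluster 2 below, 1 above
  fit <- fit_logistic(x, y)
  expect_equal(fit$analytic_threshold, 5, tolerance = 1e-6)
  expect_true(fit$separation)

  # doubling every training point leaves coefficients unchanged
  xr <- c(2, 3, 4, 5, 4.2, 5.4, 6, 7)
  yr <- c(0, 0, 1, 0, 1, 1, 0, 1)
  f1 <- fit_logistic(xr, yr)
  f2 <- fit_logistic(rep(xr, 2), rep(yr, 2))
  expect_equal(f1$intercept_term, f2$intercept_term, tolerance = 1e-6)
  expect_equal(f1$slope_term, f2$slope_term, tolerance = 1e-6)

  expect_error(fit_logistic(rep(3, 8), yr), "constant")
  expect_error(fit_logistic(xr, rep(1, 8)), "both classes")
})

test_that("predict_membership follows the exponent sign convention", {
  fit <- logistic_fit_from_terms(-6.84, 1.26)
  # boundary: x = 6.84/1.26 gives P = 0.5
  expect_equal(predict_membership(fit, 6.84 / 1.26)$probability, 0.5,
               tolerance = 1e-12)
  expect_equal(fit$analytic_threshold, 6.84 / 1.26)
  # x = 0 -> P = 1/(1 + e^-6.84) ~ 0.9989
  expect_equal(predict_membership(fit, 0)$probability,
               1 / (1 + exp(-6.84)), tolerance = 1e-12)
  # P decreases with x under these coefficients (busy sites -> cluster 1)
  pr <- predict_membership(fit, seq(0, 12, 0.5))
  expect_true(all(diff(pr$probability) < 0))
  expect_equal(pr$cluster, ifelse(pr$probability > 0.5, 2L, 1L))
  # monotone for any fit (sign flipped too)
  pr2 <- predict_membership(logistic_fit_from_terms(3, -0.8),
                            seq(0, 12, 0.5))
  expect_true(all(diff(pr2$probability) > 0))
})

test_that("confusion_metrics satisfies its identities", {
  actual <- rep(c(1, 2), c(10, 14))
  # perfect prediction
  cm <- confusion_metrics(actual, actual, positive_class = 2)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$kappa, 1)
  expect_equal(cm$balanced_accuracy, 1)

  # label-independent predictions give kappa ~ 0 over permutations
  with_seed(55, {
    ks <- replicate(300, {
      confusion_metrics(sample(actual), actual, positive_class = 2)$kappa
    })
    expect_lt(abs(mean(ks)), 0.05)
  })

  # balanced accuracy identity on every summary produced
  with_seed(56, {
    for (i in 1:20) {
      pred <- sample(1:2, 24, replace = TRUE)
      cm_i <- confusion_metrics(pred, actual, positive_class = 1)
      expect_equal(cm_i$balanced_accuracy,
                   (cm_i$sensitivity + cm_i$specificity) / 2)
      expect_equal(sum(cm_i$table), 24)
      # both conventions share accuracy and kappa
      cm_j <- confusion_metrics(pred, actual, positive_class = 2)
      expect_equal(cm_i$accuracy, cm_j$accuracy)
      expect_equal(cm_i$kappa, cm_j$kappa)
    }
  })

  # degenerate marginals: a class absent from truth
  cm_d <- confusion_metrics(rep(1, 5), rep(1, 5), positive_class = 1)
  expect_equal(cm_d$accuracy, 1)
  expect_equal(cm_d$kappa, 0)      # p_e = 1 convention
  expect_true(is.na(cm_d$specificity))
})

test_that("empirical_threshold scans midpoint cuts", {
  # {1,2,3} vs {8,9,10}: any cut in (3,8) is optimal; midpoint 5.5
  et <- empirical_threshold(c(1, 2, 3, 8, 9, 10), rep(1:2, each = 3))
  expect_equal(et$threshold, 5.5)
  expect_equal(et$misclassified, 0L)
  expect_equal(et$high_side, 2)
  # one site per cluster
  expect_equal(empirical_threshold(c(4, 6), c(1, 2))$threshold, 5)
  # invariant to adding sites far from the boundary
  et2 <- empirical_threshold(c(1, 2, 3, 8, 9, 10, 100, -50),
                             c(1, 1, 1, 2, 2, 2, 2, 1))
  expect_equal(et2$threshold, 5.5)
  # identical distributions -> undefined
  et3 <- empirical_threshold(rep(c(1, 2, 3), 2), rep(1:2, each = 3))
  expect_true(is.na(et3$threshold))
})
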