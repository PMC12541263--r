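test_that("pearson_with_p matches the textbook formulas", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      y <- 0.3 * x + rnorm(n)
      res <- pearson_with_p(x, y)
      o <- oracle_pearson(x, y)
      expect_equal(res$r, o$r, tolerance = 1e-12)
      expect_equal(res$p, o$p, tolerance = 1e-12)
      expect_equal(res$n, n)
    }
  })
  perfect <- pearson_with_p(1:10, 2 * (1:10))
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
})

test_that("pearson_with_p guards its preconditions", {
  expect_error(pearson_with_p(1:5, 1:4), "equal length")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
})

test_that("OLS matches the normal equations and exact fits", {
  withr::with_seed(2, {
    for (i in 1:10) {
      n <- 30
      X <- as.data.frame(matrix(rnorm(n * 3), n, 3))
      names(X) <- c("a", "b", "c")
      X$y <- 1 + 2 * X$a - X$b + rnorm(n)
      fit <- ols_fit(X, "y", c("a", "b", "c"))
      o <- oracle_ols(X[, c("a", "b", "c")], X$y)
      expect_equal(c(fit$intercept, fit$coefficients$estimate),
                   unname(o$coef), tolerance = 1e-8)
      expect_equal(fit$r.squared, o$r2, tolerance = 1e-8)
    }
  })
  exact <- data.frame(x = c(0, 1, 2), y = c(0, 1, 2))
  fit <- suppressWarnings(ols_fit(exact, "y", "x"))
  expect_equal(fit$intercept, 0)
  expect_equal(fit$coefficients$estimate, 1)
  expect_equal(fit$r.squared, 1)
})

test_that("OLS p-values are uniform under the null", {
  withr::with_seed(3, {
    pvals <- replicate(300, {
      d <- data.frame(x = rnorm(40), y = rnorm(40))
      ols_fit(d, "y", "x")$coefficients$p.value
    })
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("OLS rejects deficient designs by name", {
  d <- data.frame(a = rnorm(20), y = rnorm(20))
  d$b <- 2 * d$a
  expect_error(ols_fit(d, "y", c("a", "b")), "dependent columns: b")
  expect_error(ols_fit(d[1:3, ], "y", c("a", "b")), "need n > k")
})

test_that("VIF matches its closed form and flags collinearity", {
  # orthogonal centered columns -> VIF 1
  X <- data.frame(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  expect_equal(unname(vif(X)), c(1, 1))

  # two predictors with sample correlation exactly 0.9
  z1 <- c(-1, -1, 1, 1) / 2
  z2 <- c(-1, 1, -1, 1) / 2
  X9 <- data.frame(a = z1, b = 0.9 * z1 + sqrt(1 - 0.81) * z2)
  expect_equal(cor(X9$a, X9$b), 0.9, tolerance = 1e-12)
  expect_equal(unname(vif(X9)), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)

  # duplicated column -> infinite VIF
  Xd <- data.frame(a = rnorm(10))
  Xd$b <- Xd$a
  expect_equal(unname(vif(Xd)), c(Inf, Inf))

  # single predictor -> 1 by convention; constant column rejected
  expect_equal(unname(vif(data.frame(a = rnorm(5)))), 1)
  expect_error(vif(data.frame(a = rep(1, 5), b = rnorm(5))),
               "zero variance")
})

test_that("VIF agrees with the car package on random designs", {
  skip_if_not_installed("car")
  withr::with_seed(4, {
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(X) <- paste0("v", 1:4)
    X$v4 <- X$v1 + 0.5 * X$v2 + rnorm(n, 0, 0.5)
    y <- rnorm(n)
    ours <- vif(X)
    theirs <- car::vif(lm(y ~ ., data = X))
    expect_equal(unname(ours), unname(theirs[names(ours)]),
                 tolerance = 1e-10)
  })
})

test_that("correlation screen reports all pairs in canonical order", {
  co <- simulate_cohort(cohort_config(n = 30, seed = 8, duration = 30))
  f <- extract_features(co$sessions)
  sc <- score_scales(co$items)
  screen <- correlation_screen(f, sc)
  expect_equal(nrow(screen), 77)
  expect_equal(unique(screen$feature), kin_features())
  # within a feature block, |r| is non-increasing
  for (ft in kin_features()) {
    rs <- abs(screen$r[screen$feature == ft])
    rs <- rs[!is.na(rs)]
    expect_true(all(diff(rs) <= 1e-15))
  }
  expect_equal(attr(screen, "n_tests"), 77)
})

test_that("non-computable screen pairs are reported, not dropped", {
  f <- tibble::tibble(subject_id = c("a", "b", "c"),
                      average_speed = c(1, 2, 3),
                      acceleration = c(1, 1, 1))  # constant
  sc <- tibble::tibble(subject_id = c("a", "b", "c"),
                       adhd_hyperactivity = c(5, 6, 9))
  screen <- correlation_screen(f, sc)
  expect_equal(nrow(screen), 2)
  expect_false(screen$computable[screen$feature == "acceleration"])
  expect_true(screen$computable[screen$feature == "average_speed"])

  tiny <- correlation_screen(f[1:2, ], sc[1:2, ])
  expect_true(all(!tiny$computable))
})

test_that("stepwise keeps a planted predictor and drops noise", {
  withr::with_seed(5, {
    n <- 500
    X <- as.data.frame(matrix(rnorm(n * 7), n, 7))
    names(X) <- kin_features()
    X$y <- 2 * X$total_distance + rnorm(n, 0, 1)
    fit <- backward_stepwise(X, "y")
    expect_true("total_distance" %in% fit$terms$term)
    expect_gt(fit$r.squared, 0.7)
    expect_false(fit$empty_model)
    expect_true(all(fit$terms$p.value < 0.10))
  })
})

test_that("a y orthogonal to every predictor yields the empty model", {
  withr::with_seed(6, {
    n <- 40
    X <- as.data.frame(matrix(rnorm(n * 7), n, 7))
    names(X) <- kin_features()
    y0 <- rnorm(n)
    X$y <- stats::resid(lm(y0 ~ ., data = X))  # exactly orthogonal
  })
  fit <- backward_stepwise(X, "y")
  expect_true(fit$empty_model)
  expect_equal(nrow(fit$terms), 0)
  expect_true(is.na(fit$r.squared))
  expect_match(utils::capture.output(print(fit)), "—", all = FALSE)
})

test_that("stepwise boundary thresholds return full and empty models", {
  withr::with_seed(7, {
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    names(X) <- paste0("p", 1:5)
    X$y <- X$p1 + rnorm(n)
  })
  full <- backward_stepwise(X, "y", paste0("p", 1:5),
                            stepwise_config(p_enter = 0.05, p_remove = 1))
  expect_equal(full$terms$term, paste0("p", 1:5))
  empty <- backward_stepwise(X, "y", paste0("p", 1:5),
                             stepwise_config(p_enter = 0, p_remove = 0))
  expect_true(empty$empty_model)
})

test_that("aliased predictors are set aside and recorded in the trace", {
  withr::with_seed(8, {
    n <- 60
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    X$c <- 2 * X$a  # exact copy of a, up to scale
    X$y <- X$a + X$b + rnorm(n, 0, 0.5)
  })
  fit <- backward_stepwise(X, "y", c("a", "b", "c"))
  expect_true("alias" %in% fit$trace$action)
  expect_false(all(c("a", "c") %in% fit$terms$term))
  expect_false(fit$empty_model)
})

test_that("small samples start from the largest fittable model", {
  withr::with_seed(9, {
    X <- as.data.frame(matrix(rnorm(6 * 7), 6, 7))
    names(X) <- kin_features()
    X$y <- rnorm(6)
  })
  fit <- backward_stepwise(X, "y")
  expect_true("trim" %in% fit$trace$action)
  expect_lte(max(fit$trace$n_retained), 4)  # k_max = n - 2
  expect_error(backward_stepwise(X[1:3, ], "y"), "too few observations")
})

test_that("stepwise configuration is validated", {
  expect_error(stepwise_config(p_enter = 0.2, p_remove = 0.1), "p_enter")
  expect_error(stepwise_config(p_remove = 1.2), "0, 1")
})

test_that("tidy and glance summarize stepwise fits", {
  withr::with_seed(10, {
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 3), n, 3))
    names(X) <- c("average_speed", "acceleration", "total_distance")
    X$y <- X$average_speed + rnorm(n)
  })
  fit <- backward_stepwise(X, "y",
                           c("average_speed", "acceleration",
                             "total_distance"))
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "p.value", "vif"))
  gl <- generics::glance(fit)
  expect_equal(gl$outcome, "y")
  expect_equal(gl$n, n)
  expect_equal(gl$n_predictors, nrow(td))
})

test_that("run_inference executes all stages coherently", {
  co <- simulate_cohort(cohort_config(n = 40, seed = 12, duration = 60))
  f <- extract_features(co$sessions)
  sc <- score_scales(co$items)
  inf <- run_inference(f, sc)
  expect_equal(nrow(inf$descriptives), 11)
  expect_equal(nrow(inf$screen), 77)
  expect_length(inf$models, 11)
  expect_named(inf$models, kin_measures(), ignore.order = TRUE)
  # flagged VIFs only ever refer to retained predictors
  if (nrow(inf$flagged_vif) > 0) {
    for (i in seq_len(nrow(inf$flagged_vif))) {
      m <- inf$models[[inf$flagged_vif$outcome[i]]]
      expect_true(inf$flagged_vif$term[i] %in% m$terms$term)
    }
  }
  # duplicate ids rejected
  f2 <- dplyr::bind_rows(f, f[1, ])
  expect_error(run_inference(f2, sc), "duplicate subject ids")
})

test_that("tiny cohorts fail inference loudly, not silently", {
  f <- tibble::tibble(subject_id = c("a", "b"), average_speed = c(1, 2),
                      acceleration = c(3, 1), total_distance = c(2, 8),
                      area_occupied = c(1, 2), hand_head_distance = c(1, 2),
                      movement_frequency = c(0, 1), time_spent_still = c(9, 1))
  sc <- tibble::tibble(subject_id = c("a", "b"),
                       adhd_hyperactivity = c(5, 9))
  expect_error(run_inference(f, sc), "too few observations")
})
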