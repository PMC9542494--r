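test_that("disturbance codings map intervals as documented", {
  ints <- c(1, 2, 4, 8, 16)
  expect_equal(code_disturbance(ints, "events_per_16d"), c(16, 8, 4, 2, 1))
  expect_equal(code_disturbance(ints, "interval_days"), ints)
  expect_equal(code_disturbance(ints, "log2_events"), c(4, 3, 2, 1, 0))
  expect_error(code_disturbance(0), "positive")
})

test_that("OLS fits recover exact structure and match a brute-force oracle", {
  # perfect line
  d <- tibble::tibble(disturbance_interval = c(1, 2, 4), y = NA)
  d$y <- 2 * code_disturbance(d$disturbance_interval)
  f <- fit_linear_model(model_spec("y", disturbance_degree = 1), d)
  expect_equal(unname(coef(f$fit)), c(0, 2), tolerance = 1e-12)
  expect_lt(sum(residuals(f$fit)^2), 1e-20)

  # intercept-only equals the sample mean
  d2 <- tibble::tibble(y = rnorm(20))
  f2 <- fit_linear_model(model_spec("y", disturbance_degree = 0), d2)
  expect_equal(unname(coef(f2$fit)), mean(d2$y))

  # random 30 x 4 design vs normal equations solved independently
  set.seed(19)
  for (i in 1:5) {
    dat <- tibble::tibble(
      x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30),
      y = rnorm(30)
    )
    fit <- fit_linear_model(
      model_spec("y", formula = y ~ x1 + x2 + x3), dat
    )
    X <- cbind(1, dat$x1, dat$x2, dat$x3)
    beta <- solve(crossprod(X), crossprod(X, dat$y))
    expect_equal(unname(coef(fit$fit)), as.vector(beta), tolerance = 1e-8)
  }
})

test_that("rows with undefined response are excluded and counted", {
  d <- tibble::tibble(disturbance_interval = rep(c(1, 2, 4, 8), 3),
                      y = rnorm(12))
  d$y[c(2, 5)] <- NA
  f <- fit_linear_model(model_spec("y"), d)
  expect_equal(f$n, 10)
  expect_equal(f$n_excluded, 2)
})

test_that("ANOVA F agrees with classical identities", {
  # two-group one-way F equals the squared equal-variance t statistic
  d <- tibble::tibble(
    g = factor(rep(c("a", "b"), each = 6)),
    y = c(3.1, 2.7, 3.3, 2.9, 3.0, 3.2, 4.0, 3.6, 4.2, 3.8, 4.1, 3.7)
  )
  f <- fit_linear_model(model_spec("y", formula = y ~ g), d)
  tab <- anova_table(f, "II")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tab$statistic[tab$term == "g"], unname(tt$statistic)^2,
               tolerance = 1e-10)

  # identical group means give F = 0
  d0 <- d
  d0$y <- rep(c(1, 2, 3, 1, 2, 3), 2)
  f0 <- fit_linear_model(model_spec("y", formula = y ~ g), d0)
  expect_equal(anova_table(f0, "II")$statistic[1], 0, tolerance = 1e-20)
})

test_that("type II and III agree on balanced designs without interaction", {
  set.seed(23)
  d <- tidyr::expand_grid(
    resource = c("low", "high"), invader_type = c("SM", "WS"),
    rep = 1:5
  )
  d$y <- rnorm(nrow(d)) + (d$resource == "high") + 2 * (d$invader_type == "WS")
  f <- fit_linear_model(
    model_spec("y", disturbance_degree = 0,
               factors = c("resource", "invader_type"),
               interactions = "none"),
    d
  )
  t2 <- anova_table(f, "II")
  t3 <- anova_table(f, "III")
  for (term in c("resource", "invader_type")) {
    expect_equal(t2$statistic[t2$term == term], t3$statistic[t3$term == term],
                 tolerance = 1e-10)
  }
})

test_that("the Gaussian LRT has its closed form and detects nesting", {
  set.seed(29)
  d <- tibble::tibble(x = rnorm(10), z = rnorm(10))
  d$y <- 1 + 0.8 * d$x + rnorm(10, 0, 0.5)
  full <- fit_linear_model(model_spec("y", formula = y ~ x), d)
  reduced <- fit_linear_model(model_spec("y", formula = y ~ 1), d)
  out <- lrt(full, reduced)
  rss1 <- sum(residuals(full$fit)^2)
  rss0 <- sum((d$y - mean(d$y))^2)
  expect_equal(out$statistic, 10 * log(rss0 / rss1))
  expect_equal(out$df, 1)
  expect_equal(out$p_value, pchisq(10 * log(rss0 / rss1), 1, lower.tail = FALSE))

  # a model against itself: zero statistic, p = 1
  self <- lrt(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  other <- fit_linear_model(model_spec("y", formula = y ~ z), d)
  expect_error(lrt(full, other), "not nested")
})

test_that("null LRT p-values are approximately uniform", {
  set.seed(31)
  p <- replicate(500, {
    d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
    full <- fit_linear_model(model_spec("y", formula = y ~ x), d)
    reduced <- fit_linear_model(model_spec("y", formula = y ~ 1), d)
    lrt(full, reduced)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("backward LRT selection respects marginality", {
  set.seed(37)
  d <- generate_parametric(parametric_config(
    slope_by = tibble::tibble(
      resource = c("low", "medium", "high"), invader_type = "SM",
      slope = c(-0.1, 0, 0.1), intercept = 1, quad = 0.02
    ),
    residual_sd = 0.2
  ), seed = 37)
  sel <- likelihood_ratio_select(
    model_spec("log_v_plus_1", disturbance_degree = 2, factors = "resource"),
    d
  )
  labels <- attr(terms(sel$fit$fit), "term.labels")
  # no term may remain whose marginal lower-order term was dropped
  if (any(grepl("I(disturbance^2)", labels, fixed = TRUE))) {
    expect_true("disturbance" %in% labels)
  }
  if (any(grepl(":", labels))) {
    parents <- unique(unlist(strsplit(grep(":", labels, value = TRUE), ":")))
    expect_true(all(setdiff(parents, "") %in% c(labels, "I(disturbance^2)")))
  }
  # with a strong disturbance x resource interaction it must be retained
  expect_true(any(grepl("disturbance:resource", labels, fixed = TRUE)))
  expect_true(all(c("step", "term", "p_value", "dropped") %in%
                    colnames(sel$trace)))
})

test_that("per-resource slopes are exact on noiseless generated data", {
  d <- generate_parametric(
    parametric_config(
      slope_by = dplyr::filter(reported_slope_set(), invader_type == "SM"),
      residual_sd = 0
    ),
    seed = 1
  )
  f <- fit_linear_model(model_spec("log_v_plus_1", factors = "resource"), d)
  sl <- suppressWarnings(resource_specific_slopes(f)) # noiseless fit is exact
  truth <- dplyr::filter(reported_slope_set(), invader_type == "SM")
  sl <- sl[match(truth$resource, sl$resource), ]
  expect_equal(sl$slope, truth$slope, tolerance = 1e-8)
  expect_equal(sl$ci_hi - sl$ci_lo, rep(0, 3), tolerance = 1e-8)
})

test_that("slopes without an interaction are common across levels", {
  set.seed(43)
  d <- generate_parametric(parametric_config(residual_sd = 0.3), seed = 43)
  f <- fit_linear_model(
    model_spec("log_v_plus_1", factors = "resource", interactions = "none"),
    d
  )
  sl <- resource_specific_slopes(f)
  expect_equal(length(unique(round(sl$slope, 12))), 1)

  fq <- fit_linear_model(
    model_spec("log_v_plus_1", disturbance_degree = 2, factors = "resource"),
    d
  )
  expect_error(resource_specific_slopes(fq), "curvature")
})

test_that("marginal pairwise comparisons use Bonferroni arithmetic", {
  set.seed(47)
  d <- generate_parametric(parametric_config(residual_sd = 0.5), seed = 47)
  f <- fit_linear_model(
    model_spec("log_v_plus_1", disturbance_degree = 0, factors = "resource"),
    d
  )
  pw <- marginal_pairwise(f, "resource")
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_raw), tolerance = 1e-12)

  # balanced one-factor design: marginal means equal raw group means
  means <- tapply(f$data$log_v_plus_1, f$data$resource, mean)
  for (i in seq_len(nrow(pw))) {
    expect_equal(pw$estimate[i],
                 unname(means[pw$level_a[i]] - means[pw$level_b[i]]),
                 tolerance = 1e-10)
  }

  expect_error(marginal_pairwise(f, "invader_type"), "categorical")

  # duplicated levels differ by nothing
  d2 <- dplyr::mutate(d, y2 = 1.5)
  f2 <- fit_linear_model(
    model_spec("y2", disturbance_degree = 0, factors = "resource"), d2
  )
  pw2 <- suppressWarnings(marginal_pairwise(f2, "resource")) # constant response
  expect_equal(pw2$estimate, rep(0, 3), tolerance = 1e-12)
})
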