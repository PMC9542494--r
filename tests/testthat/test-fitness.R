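test_that("resident series imputation follows the mortality-division rules", {
  s2 <- impute_resident_series(1e8, 2)
  expect_equal(s2$resident_density, rep(1e8, 3))
  expect_true(all(s2$provenance == "assumed-equal"))

  s16 <- impute_resident_series(5e7, 16)
  expect_equal(s16$resident_density, rep(5e9, 3))
  expect_true(all(s16$provenance == "imputed-by-mortality-division"))

  s8 <- impute_resident_series(5e7, 8)
  expect_equal(s8$resident_density, c(5e9, 5e7, 5e9))
  expect_equal(s8$day, c(4L, 8L, 12L))

  expect_error(impute_resident_series(1e8, 3), "disturbance_interval")
})

test_that("imputation inverts one simulated disturbance exactly", {
  set.seed(7)
  for (i in 1:20) {
    f <- runif(1, 0.001, 0.5)
    true_undisturbed <- 10^runif(1, 5, 10)
    measured <- true_undisturbed * f # what survives one disturbance
    s <- impute_resident_series(measured, 16, mortality_model(f))
    expect_equal(s$resident_density, rep(true_undisturbed, 3))
  }
})

test_that("initial invader proportion averages per-event frequencies", {
  sched <- invasion_schedule("SM", invader_density_added = 1e7)
  expect_equal(initial_invader_proportion(sched, rep(1e7, 3)), 0.5)
  expect_equal(initial_invader_proportion(sched, rep(9e7, 3)), 0.1)

  none <- invasion_schedule("SM", invader_density_added = 0)
  expect_equal(initial_invader_proportion(none, rep(1e7, 3)), 0)
  expect_error(initial_invader_proportion(none, rep(0, 3)), "undefined")

  # invariant to common rescaling of all densities
  set.seed(11)
  for (i in 1:15) {
    I <- runif(3, 1e4, 1e7)
    R <- runif(3, 1e5, 1e9)
    k <- 10^runif(1, -3, 3)
    s1 <- invasion_schedule("SM", invader_density_added = I)
    sk <- invasion_schedule("SM", invader_density_added = k * I)
    expect_equal(
      initial_invader_proportion(s1, R),
      initial_invader_proportion(sk, k * R)
    )
  }
})

test_that("default schedules split the printed inoculum totals over events", {
  expect_equal(sum(invasion_schedule("SM")$invader_density_added) * 6, 8.1e6)
  expect_equal(sum(invasion_schedule("WS")$invader_density_added) * 6, 6.6e6)
  expect_equal(invasion_schedule("SM")$invasion_days, c(4L, 8L, 12L))
})

test_that("relative fitness v is the odds ratio of proportions", {
  expect_equal(relative_fitness_v(0.3, 0.3), 1)
  expect_equal(relative_fitness_v(0.5, 0), 0)
  expect_equal(relative_fitness_v(0.2, 0.5), 4)
  expect_true(is.na(relative_fitness_v(0.2, 1))) # fixation flagged, not Inf
  expect_error(relative_fitness_v(0, 0.5), "x1 = 0")
  expect_error(relative_fitness_v(0.5, 1.2), "out of range")

  # antisymmetry: v(a, b) * v(b, a) = 1
  set.seed(3)
  a <- runif(20, 0.01, 0.99)
  b <- runif(20, 0.01, 0.99)
  expect_equal(relative_fitness_v(a, b) * relative_fitness_v(b, a),
               rep(1, 20))
})

test_that("success score is ln(v + 1) with threshold at equal growth", {
  s <- success_score(c(1, 0, exp(1) - 1))
  expect_equal(round(s$log_v_plus_1[1], 2), 0.69)
  expect_equal(s$log_v_plus_1[2], 0)
  expect_equal(s$log_v_plus_1[3], 1)
  # flag flips exactly at v = 1
  expect_false(success_score(1)$increased)
  expect_true(success_score(1 + 1e-9)$increased)
  expect_false(success_score(1 - 1e-9)$increased)
  # strictly increasing in v
  v <- sort(runif(20, 0, 50))
  expect_true(all(diff(success_score(v)$log_v_plus_1) > 0))
  expect_error(success_score(-1), "non-negative")
})

test_that("the fitness pipeline equals manual composition of its steps", {
  fx <- oracle_fixture()
  ft <- compute_fitness_table(fx$counts, fx$day4)
  expect_equal(nrow(ft), 1)

  series <- impute_resident_series(5e7, 2)
  x1 <- initial_invader_proportion(invasion_schedule("SM"), series)
  x2 <- (5e8 + 1) / (5e8 + 1 + 1e9)
  v <- relative_fitness_v(x1, x2)
  expect_equal(ft$x1, x1)
  expect_equal(ft$x2, x2)
  expect_equal(ft$v, v)
  expect_equal(ft$log_v_plus_1, log(v + 1))
  expect_true(ft$increased)
})

test_that("matched initial and final proportions give v = 1", {
  counts <- as_count_table(dplyr::bind_rows(
    count_row(population = "resident", colony_count = 60),
    count_row(population = "invader", colony_count = 60)
  ))
  day4 <- as_count_table(
    count_row(microcosm_id = "r1", day = 4, invader_type = NA_character_,
              colony_count = 60)
  )
  sched <- list(SM = invasion_schedule("SM", invader_density_added = 1e9))
  ft <- compute_fitness_table(counts, day4, schedules = sched)
  expect_equal(ft$x1, 0.5)
  expect_equal(ft$v, 1, tolerance = 1e-8)
  expect_equal(ft$log_v_plus_1, log(2), tolerance = 1e-8)
})

test_that("an extinct invader scores near zero through the +1 offset", {
  counts <- as_count_table(dplyr::bind_rows(
    count_row(population = "resident", colony_count = 60),
    count_row(population = "invader", colony_count = 0)
  ))
  day4 <- as_count_table(
    count_row(microcosm_id = "r1", day = 4, invader_type = NA_character_,
              colony_count = 30, dilution = 1e-5)
  )
  ft <- compute_fitness_table(counts, day4)
  expect_lt(ft$x2, 1e-8)
  expect_lt(ft$log_v_plus_1, 1e-3)
  expect_false(ft$increased)

  # alternative reading: no density offset, v collapses to exactly 0
  ft0 <- compute_fitness_table(counts, day4, offset_mode = "none")
  expect_equal(ft0$v, 0)
  expect_equal(ft0$log_v_plus_1, 0)
})

test_that("a missing day-4 reference cell is a named error", {
  fx <- oracle_fixture()
  wrong_cell <- fx$day4
  wrong_cell$disturbance_interval <- 8L
  wrong_cell$day <- 4L
  expect_error(
    compute_fitness_table(fx$counts, as_count_table(wrong_cell)),
    "resource = high"
  )
})
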