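test_that("identical seeds give identical experiments", {
  a <- simulate_experiment(seed = 5, replicates = 1, reference_replicates = 1)
  b <- simulate_experiment(seed = 5, replicates = 1, reference_replicates = 1)
  expect_equal(as.data.frame(a$counts), as.data.frame(b$counts))
  expect_equal(as.data.frame(a$day4_reference), as.data.frame(b$day4_reference))

  c <- simulate_experiment(seed = 6, replicates = 1, reference_replicates = 1)
  expect_false(identical(a$counts$colony_count, c$counts$colony_count))
})

test_that("adding replicates never perturbs existing ones", {
  two <- simulate_experiment(seed = 9, replicates = 2, reference_replicates = 1)
  three <- simulate_experiment(seed = 9, replicates = 3, reference_replicates = 1)
  sub <- dplyr::filter(three$counts, replicate <= 2)
  expect_equal(
    as.data.frame(dplyr::arrange(sub, microcosm_id, population, morphotype)),
    as.data.frame(dplyr::arrange(two$counts, microcosm_id, population,
                                 morphotype))
  )
})

test_that("each disturbance multiplies every population by the transfer fraction", {
  for (interval in c(1, 4, 8)) {
    traj <- simulate_microcosm("high", interval, "SM", seed = 2,
                               demographic_noise = FALSE)
    events <- dplyr::filter(
      traj, day %% interval == 0,
      population == "resident", density > 0
    )
    expect_equal(events$density_post / events$density,
                 rep(0.01, nrow(events)), tolerance = 1e-12)
    # intensity-equal design: floor(16 / d) events in 16 days
    expect_equal(length(unique(events$day)), floor(16 / interval))
  }
})

test_that("a closed system without mutation stays pure SM", {
  cfg <- simulation_config(mutation_sm_to_ws = 0, mutation_sm_to_fs = 0)
  traj <- simulate_microcosm("medium", 4, NA, cfg, seed = 3,
                             demographic_noise = FALSE)
  others <- dplyr::filter(traj, morphotype != "SM")
  expect_true(all(others$density == 0))
  final <- dplyr::filter(traj, day == 16, population == "resident")
  expect_equal(
    simpson_index(setNames(final$density, final$morphotype))$simpson_D, 0
  )
})

test_that("without disturbance or toxicity the total approaches capacity", {
  cfg <- simulation_config(
    toxicity = c(low = 0, medium = 0, high = 0),
    mutation_sm_to_ws = 0, mutation_sm_to_fs = 0
  )
  for (res in c("low", "medium", "high")) {
    traj <- simulate_microcosm(res, 16, NA, cfg, seed = 4,
                               demographic_noise = FALSE)
    total16 <- sum(dplyr::filter(traj, day == 16)$density)
    K <- cfg$carrying_capacity[[res]]
    expect_lt(abs(total16 - K) / K, 0.01)
  }
})

test_that("the default experiment matches the study design", {
  sim <- simulate_experiment(seed = 1, replicates = 1, reference_replicates = 1)
  d <- validate_design(sim$counts)
  expect_equal(d$n_microcosms, 30)
  expect_equal(nrow(d$missing_cells), 0)
  dref <- validate_design(sim$day4_reference)
  expect_equal(dref$n_microcosms, 15)
  expect_true(all(sim$counts$day == 16))
  expect_true(all(sim$day4_reference$day == 4))
  expect_true(all(sim$day4_reference$population == "resident"))
})

test_that("plate counts reflect latent densities within Poisson error", {
  sim <- simulate_experiment(seed = 12, replicates = 1,
                             reference_replicates = 1)
  joined <- dplyr::inner_join(
    dplyr::mutate(sim$counts,
                  measured = cfu_per_ml(colony_count, dilution,
                                        plated_volume_ml)),
    sim$truth,
    by = c("microcosm_id", "population", "morphotype")
  )
  informative <- dplyr::filter(
    joined, density * dilution * plated_volume_ml > 5
  )
  lambda <- with(informative, density * dilution * plated_volume_ml)
  z <- (informative$colony_count - lambda) / sqrt(lambda)
  # demographic noise adds variance beyond counting alone, so allow slack
  expect_gt(mean(abs(z) < 4), 0.9)
})
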