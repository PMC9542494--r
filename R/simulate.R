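#' Configuration of the mechanistic serial-transfer simulator
#'
#' A deliberately phenomenological model of static bacterial microcosms under
#' pulse disturbance: per-morphotype logistic competitive growth toward a
#' shared, resource-dependent carrying capacity; a density-dependent
#' stationary-phase mortality term (metabolite toxicity / oxygen depletion)
#' that is strongest at high resource concentration; a multiplicative fitness
#' bonus for the mat-forming WS morphotype once total density exceeds a
#' threshold fraction of capacity (mat formation requires a threshold
#' density); slow mutational flux from SM to WS and FS; disturbance events
#' every `disturbance_interval` days that multiply every population by
#' `transfer_fraction`; and invader inocula added immediately after the
#' disturbance on the invasion days.
#'
#' Defaults emulate the design conditions: 16 days, 1% transfer
#' (99% mortality), three resource levels spanning two orders of magnitude of
#' carrying capacity, invasions on days 4/8/12 with per-event inocula of
#' 2.7e6 (SM) and 2.2e6 (WS) cfu in the 6-ml microcosm (one third of the
#' totals added over the three events).
#'
#' @param duration_days experiment length (default 16).
#' @param transfer_fraction fraction surviving a disturbance (default 0.01).
#' @param carrying_capacity named cfu/ml per resource level.
#' @param base_growth named SM max growth rate (per day) per resource level.
#' @param morph_growth named growth-rate multiplier per morphotype.
#' @param toxicity named maximal stationary-phase death rate (per day) per
#'   resource level; realised death is `toxicity * (N/K)^2`.
#' @param mutation_sm_to_ws,mutation_sm_to_fs per-capita per-day rates.
#' @param biofilm_threshold_fraction fraction of `K` above which WS gains the
#'   mat bonus.
#' @param ws_density_bonus multiplier applied to the WS daily growth factor
#'   above the threshold (the mat gives access to the oxygen-rich interface).
#' @param mat_toxicity_protection multiple of the stationary-phase death rate
#'   the WS mat recovers while above the threshold: 1 means full escape from
#'   the toxic broth, values above 1 mean the oxygen-rich interface is
#'   actively favourable, so the mat advantage grows with broth hostility
#'   (hence with resource concentration).
#' @param invader_lag_days named integer per resource level: days of
#'   physiological lag before a freshly added inoculum (grown overnight in
#'   rich medium) starts growing in the destination medium. The downshift to
#'   dilute medium is large, so the lag lengthens as resources decrease;
#'   lagged cells are still exposed to disturbance mortality.
#' @param steps_per_day sub-daily integration steps for the growth dynamics
#'   (disturbance, invasion, sampling and demographic noise stay daily).
#' @param init_resident_density starting resident SM density, cfu/ml.
#' @param invasion_days days on which invaders are added (post-disturbance).
#' @param inoculum_cfu named total cfu added per invasion event per invader
#'   type.
#' @param plated_volume_ml volume spread per plate.
#' @param max_expected_colonies upper edge of the target colony-count window
#'   used to choose the decade dilution.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    duration_days = 16,
    transfer_fraction = 0.01,
    carrying_capacity = c(low = 5e7, medium = 5e8, high = 5e9),
    base_growth = c(low = 5.0, medium = 5.1, high = 5.2),
    morph_growth = c(SM = 1, WS = 0.75, FS = 0.6),
    toxicity = c(low = 0.06, medium = 0.25, high = 0.40),
    mutation_sm_to_ws = 5e-4,
    mutation_sm_to_fs = 5e-5,
    biofilm_threshold_fraction = 0.5,
    ws_density_bonus = 1.05,
    mat_toxicity_protection = 1.75,
    invader_lag_days = c(low = 2, medium = 1, high = 0),
    init_resident_density = 5e7,
    invasion_days = INVASION_DAYS,
    inoculum_cfu = c(SM = 2.7e6, WS = 2.2e6),
    plated_volume_ml = 0.06,
    max_expected_colonies = 300,
    steps_per_day = 4) {
  stopifnot(
    transfer_fraction > 0, transfer_fraction < 1,
    all(carrying_capacity > 0), all(base_growth > 0),
    all(morph_growth > 0), all(toxicity >= 0),
    mutation_sm_to_ws >= 0, mutation_sm_to_fs >= 0,
    ws_density_bonus > 0, all(inoculum_cfu >= 0)
  )
  structure(as.list(environment()), class = "simulation_config")
}

# Poisson draw that tolerates huge means (normal approximation above 1e6)
rpois_safe <- function(lambda) {
  out <- numeric(length(lambda))
  small <- lambda <= 1e6
  out[small] <- rpois(sum(small), lambda[small])
  if (any(!small)) {
    out[!small] <- pmax(0, rnorm(sum(!small), lambda[!small],
                                 sqrt(lambda[!small])))
  }
  out
}

#' Simulate one microcosm
#'
#' Discrete-day update of resident and invader populations split by
#' morphotype (SM, WS, FS). Each day the populations grow, mutate, and are
#' optionally perturbed by Poisson demographic noise on whole-microcosm cell
#' numbers; the end-of-day state is recorded (`density`), then any
#' disturbance due that day multiplies all populations by the transfer
#' fraction and any invasion due adds the inoculum, giving the post-event
#' state (`density_post`). Final-day sampling therefore reads the
#' pre-disturbance `density`; the day-4 reference reads `density_post`.
#' Identical seeds give identical trajectories.
#'
#' @param resource `"low"`, `"medium"` or `"high"`.
#' @param disturbance_interval days between disturbances (1, 2, 4, 8 or 16).
#' @param invader_type `"SM"`, `"WS"` or `NA` for an uninvaded microcosm.
#' @param config a [simulation_config()].
#' @param seed integer seed for this microcosm's random stream.
#' @param demographic_noise apply Poisson noise to daily cell numbers.
#' @return a tibble with `day`, `population`, `morphotype`, `density`,
#'   `density_post` (cfu/ml).
#' @export
simulate_microcosm <- function(resource, disturbance_interval,
                               invader_type = NA, config = simulation_config(),
                               seed = 1, demographic_noise = TRUE) {
  stopifnot(resource %in% RESOURCE_LEVELS,
            disturbance_interval %in% DISTURBANCE_INTERVALS)
  set.seed(seed)
  K <- config$carrying_capacity[[resource]]
  r0 <- config$base_growth[[resource]]
  tox <- config$toxicity[[resource]]
  vol <- MICROCOSM_VOLUME_ML

  state <- matrix(
    0, nrow = 2, ncol = 3,
    dimnames = list(POPULATIONS, MORPHOTYPES)
  )
  state["resident", "SM"] <- config$init_resident_density

  days <- seq_len(config$duration_days)
  rec_pre <- matrix(0, nrow = length(days), ncol = 6)
  rec_post <- matrix(0, nrow = length(days), ncol = 6)
  dt <- 1 / config$steps_per_day
  log_bonus <- log(config$ws_density_bonus)
  lag_days <- config$invader_lag_days[[resource]]
  # inoculum cohorts still in physiological lag: density by maturation day
  lag_queue <- numeric(0)

  for (day in days) {
    matured <- as.integer(names(lag_queue)) < day
    if (any(matured)) {
      state["invader", invader_type] <- state["invader", invader_type] +
        sum(lag_queue[matured])
      lag_queue <- lag_queue[!matured]
    }
    for (step in seq_len(config$steps_per_day)) {
      ntot <- sum(state) + sum(lag_queue)
      avail <- max(0, 1 - ntot / K)
      crowd <- min(ntot / K, 1.5)
      growth <- r0 * config$morph_growth * avail
      other <- rep(-tox * crowd^2, 3)
      names(other) <- names(growth)
      if (ntot > config$biofilm_threshold_fraction * K) {
        other[["WS"]] <- other[["WS"]] + log_bonus +
          tox * crowd^2 * config$mat_toxicity_protection
      }
      # logistic growth, with the increment capped so growth alone never
      # carries the community past K (mat dynamics and death still can)
      grown <- sweep(state, 2, exp(growth[MORPHOTYPES] * dt), `*`)
      ntot_g <- sum(grown) + sum(lag_queue)
      if (ntot_g > K && ntot_g > ntot) {
        keep <- (max(K, ntot) - ntot) / (ntot_g - ntot)
        grown <- state + (grown - state) * keep
      }
      state <- sweep(grown, 2, exp(other[MORPHOTYPES] * dt), `*`)
      # mutational flux out of SM, within each population
      d_ws <- state[, "SM"] * config$mutation_sm_to_ws * dt
      d_fs <- state[, "SM"] * config$mutation_sm_to_fs * dt
      state[, "SM"] <- state[, "SM"] - d_ws - d_fs
      state[, "WS"] <- state[, "WS"] + d_ws
      state[, "FS"] <- state[, "FS"] + d_fs
    }
    if (demographic_noise) {
      state[] <- rpois_safe(as.vector(state) * vol) / vol
    }
    pre <- state
    pre_lagged <- sum(lag_queue)

    if (day %% disturbance_interval == 0) {
      state <- state * config$transfer_fraction
      lag_queue <- lag_queue * config$transfer_fraction
    }
    if (!is.na(invader_type) && day %in% config$invasion_days) {
      dens <- config$inoculum_cfu[[invader_type]] / vol
      if (lag_days > 0) {
        lag_queue <- c(lag_queue, setNames(dens, day + lag_days))
      } else {
        state["invader", invader_type] <- state["invader", invader_type] + dens
      }
    }
    # lagged inoculum cells are part of the countable invader population
    rec_pre[day, ] <- as.vector(pre)
    rec_post[day, ] <- as.vector(state)
    if (!is.na(invader_type)) {
      sel <- which(POPULATIONS == "invader") +
        2 * (which(MORPHOTYPES == invader_type) - 1)
      rec_pre[day, sel] <- rec_pre[day, sel] + pre_lagged
      rec_post[day, sel] <- rec_post[day, sel] + sum(lag_queue)
    }
  }
  tibble::tibble(
    day = rep(days, each = 6),
    population = rep(POPULATIONS, times = 3 * length(days)),
    morphotype = rep(rep(MORPHOTYPES, each = 2), times = length(days)),
    density = as.vector(t(rec_pre)),
    density_post = as.vector(t(rec_post))
  )
}

# choose a decade dilution so expected total colonies fall at or below the
# window top, then Poisson-sample (or round, noise off) per category
plate_state <- function(densities, config, plating_noise = TRUE) {
  vol <- config$plated_volume_ml
  total <- sum(densities)
  k <- if (total * vol > config$max_expected_colonies) {
    ceiling(log10(total * vol / config$max_expected_colonies))
  } else {
    0
  }
  dil <- 10^(-k)
  lambda <- densities * dil * vol
  counts <- if (plating_noise) rpois_safe(lambda) else round(lambda)
  tibble::tibble(
    colony_count = counts,
    dilution = dil,
    plated_volume_ml = vol
  )
}

#' Simulate the full factorial invasion experiment
#'
#' Runs [simulate_microcosm()] for every cell of the design (3 resource
#' levels x 5 disturbance intervals x 2 invader types x `replicates`,
#' defaults to the 180-microcosm design) plus `reference_replicates`
#' uninvaded microcosms per resource-by-disturbance cell sacrificed on day 4.
#' Per-microcosm seeds are derived from the master seed by stable hashing of
#' the treatment labels, so adding replicates never perturbs existing ones.
#' Final-day (and day-4 reference) densities are converted to plate counts at
#' a dilution targeting the colony-count window, with Poisson counting noise.
#'
#' @param config a [simulation_config()].
#' @param seed master seed.
#' @param replicates invaded replicates per treatment cell (default 6).
#' @param reference_replicates day-4 sacrifice replicates per resource x
#'   disturbance cell (default 3).
#' @param demographic_noise,plating_noise noise switches.
#' @return a list with `counts` (final-day [count-table]), `day4_reference`
#'   (day-4 [count-table]) and `truth` (latent densities per microcosm).
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1,
                                replicates = 6, reference_replicates = 3,
                                demographic_noise = TRUE,
                                plating_noise = TRUE) {
  final_day <- config$duration_days

  invaded <- tidyr::expand_grid(
    resource = RESOURCE_LEVELS,
    disturbance_interval = DISTURBANCE_INTERVALS,
    invader_type = INVADER_TYPES,
    replicate = seq_len(replicates)
  )
  invaded$microcosm_id <- paste0(
    invaded$resource, "_d", invaded$disturbance_interval, "_",
    invaded$invader_type, "_r", invaded$replicate
  )

  sim_one <- function(i) {
    row <- invaded[i, ]
    traj <- simulate_microcosm(
      row$resource, row$disturbance_interval, row$invader_type,
      config = config,
      seed = derive_seed(seed, row$resource, row$disturbance_interval,
                         row$invader_type, row$replicate),
      demographic_noise = demographic_noise
    )
    fin <- dplyr::filter(traj, .data$day == final_day)
    plate <- plate_state(fin$density, config, plating_noise)
    list(
      counts = dplyr::bind_cols(
        row[rep(1, nrow(fin)), ],
        day = final_day,
        fin[, c("population", "morphotype")],
        plate
      ),
      truth = dplyr::bind_cols(
        row[rep(1, nrow(fin)), ],
        day = final_day,
        fin[, c("population", "morphotype", "density")]
      )
    )
  }
  sims <- lapply(seq_len(nrow(invaded)), sim_one)

  reference <- tidyr::expand_grid(
    resource = RESOURCE_LEVELS,
    disturbance_interval = DISTURBANCE_INTERVALS,
    replicate = seq_len(reference_replicates)
  )
  reference$microcosm_id <- paste0(
    "ref_", reference$resource, "_d", reference$disturbance_interval,
    "_r", reference$replicate
  )

  ref_one <- function(i) {
    row <- reference[i, ]
    traj <- simulate_microcosm(
      row$resource, row$disturbance_interval, NA,
      config = config,
      seed = derive_seed(seed, "ref", row$resource,
                         row$disturbance_interval, row$replicate),
      demographic_noise = demographic_noise
    )
    # sacrifice on day 4, after any disturbance due that day (as invaded)
    d4 <- dplyr::filter(traj, .data$day == 4, .data$population == "resident")
    plate <- plate_state(d4$density_post, config, plating_noise)
    dplyr::bind_cols(
      row[rep(1, nrow(d4)), ],
      invader_type = NA_character_,
      day = 4,
      d4[, c("population", "morphotype")],
      plate
    )
  }
  refs <- dplyr::bind_rows(lapply(seq_len(nrow(reference)), ref_one))

  counts <- dplyr::bind_rows(lapply(sims, `[[`, "counts"))
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  list(
    counts = as_count_table(counts[, count_columns()]),
    day4_reference = as_count_table(refs[, count_columns()]),
    truth = truth
  )
}
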