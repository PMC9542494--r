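#' Invasion schedule
#'
#' Invaders are added on fixed days (by default days 4, 8 and 12, always
#' immediately after any disturbance). `invader_density_added` gives the
#' density each invasion event contributes to the 6-ml microcosm, in cfu/ml.
#' The defaults split the total inoculum over the three events evenly:
#' SM 8.1e6 cfu total and WS 6.6e6 cfu total, i.e. 2.7e6 and 2.2e6 cfu per
#' event, divided by the 6-ml culture volume.
#'
#' @param invader_type `"SM"` or `"WS"`; sets the default per-event density.
#' @param invasion_days strictly increasing integer days.
#' @param invader_density_added numeric vector (recycled) of per-event
#'   densities in cfu/ml; overrides the type default.
#' @return a list of class `invasion_schedule`.
#' @export
invasion_schedule <- function(invader_type = c("SM", "WS"),
                              invasion_days = INVASION_DAYS,
                              invader_density_added = NULL) {
  invader_type <- match.arg(invader_type)
  if (is.unsorted(invasion_days, strictly = TRUE)) {
    stop("invasion_days must be strictly increasing", call. = FALSE)
  }
  if (is.null(invader_density_added)) {
    total_cfu <- c(SM = 8.1e6, WS = 6.6e6)[[invader_type]]
    invader_density_added <- total_cfu / length(invasion_days) / MICROCOSM_VOLUME_ML
  }
  invader_density_added <- rep_len(invader_density_added, length(invasion_days))
  if (any(invader_density_added < 0)) {
    stop("invader densities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      invader_type = invader_type,
      invasion_days = as.integer(invasion_days),
      invader_density_added = setNames(invader_density_added,
                                       as.character(invasion_days))
    ),
    class = "invasion_schedule"
  )
}

#' Disturbance mortality model
#'
#' A pulse disturbance transfers `transfer_fraction` of the homogenised
#' culture into fresh medium; the default 0.01 corresponds to 99% mortality.
#'
#' @param transfer_fraction fraction surviving one disturbance, in `(0, 1)`.
#' @return a list of class `mortality_model`.
#' @export
mortality_model <- function(transfer_fraction = 0.01) {
  stopifnot(
    is.numeric(transfer_fraction), length(transfer_fraction) == 1,
    transfer_fraction > 0, transfer_fraction < 1
  )
  structure(list(transfer_fraction = transfer_fraction),
            class = "mortality_model")
}

#' Impute the resident-density series at the invasion days
#'
#' Resident densities on days 8 and 12 cannot be measured without destroying
#' undisturbed microcosms, so they are reconstructed from the day-4 reference
#' density of the matching treatment cell:
#'
#' * intervals 1, 2, 4 days: the community is disturbed at least every 4 days,
#'   so the day-4 (post-disturbance, as-invaded) density is assumed to hold on
#'   days 8 and 12 as well (`assumed-equal`);
#' * interval 16 days: the culture is never disturbed before the end, so all
#'   three densities equal the 4-day treatment's measured density divided by
#'   the disturbance survival fraction (`imputed-by-mortality-division`);
#' * interval 8 days: days 4 and 12 are undisturbed (measured / fraction),
#'   while the day-8 invasion follows the day-8 disturbance, so the day-8
#'   density is multiplied back down by the survival fraction.
#'
#' @param measured_R4 day-4 reference resident density, cfu/ml. For intervals
#'   8 and 16 this must be the 4-day treatment's measurement.
#' @param disturbance_interval one of 1, 2, 4, 8, 16 days.
#' @param mortality a [mortality_model()].
#' @param invasion_days days the series must cover (default 4, 8, 12).
#' @return a tibble of class `resident_series` with columns `day`,
#'   `resident_density` and `provenance`.
#' @export
impute_resident_series <- function(measured_R4, disturbance_interval,
                                   mortality = mortality_model(),
                                   invasion_days = INVASION_DAYS) {
  stopifnot(is.numeric(measured_R4), length(measured_R4) == 1, measured_R4 >= 0)
  if (!disturbance_interval %in% DISTURBANCE_INTERVALS) {
    stop(
      "disturbance_interval must be one of ",
      paste(DISTURBANCE_INTERVALS, collapse = ", "),
      call. = FALSE
    )
  }
  f <- mortality$transfer_fraction
  if (disturbance_interval <= 4) {
    dens <- rep(measured_R4, length(invasion_days))
    prov <- rep("assumed-equal", length(invasion_days))
  } else if (disturbance_interval == 16) {
    dens <- rep(measured_R4 / f, length(invasion_days))
    prov <- rep("imputed-by-mortality-division", length(invasion_days))
  } else { # interval 8: disturbed on day 8 just before that invasion
    undisturbed <- measured_R4 / f
    dens <- ifelse(invasion_days %% 8 == 0, f * undisturbed, undisturbed)
    prov <- rep("imputed-by-mortality-division", length(invasion_days))
  }
  out <- tibble::tibble(
    day = as.integer(invasion_days),
    resident_density = dens,
    provenance = prov
  )
  class(out) <- c("resident_series", class(out))
  out
}

#' Initial invader proportion averaged over invasion events
#'
#' The initial invader proportion `x1` is the mean over invasion days of
#' `I_t / (I_t + R_t)`, where `I_t` is the invader density added on day `t`
#' and `R_t` the resident density being invaded on that day.
#'
#' @param schedule an [invasion_schedule()].
#' @param residents a `resident_series` from [impute_resident_series()], or a
#'   numeric vector of resident densities aligned with the invasion days.
#' @return `x1`, a proportion in `[0, 1]`.
#' @export
initial_invader_proportion <- function(schedule, residents) {
  I_t <- schedule$invader_density_added
  R_t <- if (is.data.frame(residents)) {
    idx <- match(schedule$invasion_days, residents$day)
    if (anyNA(idx)) {
      stop("resident series does not cover all invasion days", call. = FALSE)
    }
    residents$resident_density[idx]
  } else {
    rep_len(residents, length(I_t))
  }
  tot <- I_t + R_t
  if (all(tot == 0)) {
    stop("undefined proportion: no invaders or residents on any invasion day",
         call. = FALSE)
  }
  if (any(tot == 0)) {
    stop("invasion day with zero invader and resident density", call. = FALSE)
  }
  mean(I_t / tot)
}

#' Relative invader fitness v (proportional change)
#'
#' The odds-ratio-style change in invader proportion over the experiment:
#' `v = x2 (1 - x1) / (x1 (1 - x2))`. `v > 1` means the invader increased in
#' proportion; `v = 1` means invader and residents grew equally.
#'
#' @param x1 initial invader proportion, strictly inside `(0, 1)`.
#' @param x2 final invader proportion in `[0, 1]`. Exact fixation (`x2 = 1`)
#'   is returned as `NA` (flagged undefined) rather than infinity.
#' @return `v >= 0`, vectorised over `x1`, `x2`.
#' @export
relative_fitness_v <- function(x1, x2) {
  if (any(x1 <= 0)) {
    stop("x1 = 0: no invader introduced, v is undefined", call. = FALSE)
  }
  if (any(x1 >= 1) || any(x2 < 0) || any(x2 > 1)) {
    stop("proportions out of range: need x1 in (0,1), x2 in [0,1]",
         call. = FALSE)
  }
  v <- x2 * (1 - x1) / (x1 * (1 - x2))
  v[x2 == 1] <- NA_real_
  v
}

#' Invasion-success score log(v + 1)
#'
#' The natural-log transform `s = ln(v + 1)` normalises the residuals of the
#' success models. Scores above `ln 2` (0.69 to 2 dp) indicate that the
#' invader increased in proportion over the experiment (`v > 1`).
#'
#' @param v relative fitness from [relative_fitness_v()]; `NA` propagates.
#' @return a tibble with `v`, `log_v_plus_1`, `increased`.
#' @export
success_score <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("v must be non-negative", call. = FALSE)
  s <- log(v + 1)
  tibble::tibble(v = v, log_v_plus_1 = s, increased = s > log(2))
}

#' Zero-inflation offset for final invader densities
#'
#' Adds a fixed density offset (default 1 cfu/ml, applied after volume
#' standardisation) to the final invader density so that microcosms where the
#' invader fell below detection yield a small positive final proportion
#' instead of exactly zero.
#'
#' @param final_invader_density cfu/ml.
#' @param offset cfu/ml added (default 1).
#' @return adjusted density.
#' @export
apply_zero_offset <- function(final_invader_density, offset = 1) {
  stopifnot(offset >= 0)
  final_invader_density + offset
}

#' Compute the per-microcosm fitness table
#'
#' Runs the full invasion-success calculation for every invaded microcosm:
#' the initial proportion `x1` from the invasion schedule and the
#' treatment-level imputed resident series ([impute_resident_series()]), the
#' final proportion `x2` from that microcosm's final-day counts (all
#' morphotypes pooled within each population, the zero-inflation offset
#' applied to the invader density), then `v` and the success score.
#'
#' The day-4 reference is averaged over the sacrifice replicates of each
#' (resource, disturbance) cell; intervals 8 and 16 days use the 4-day
#' treatment's reference of the same resource level, per the imputation rule.
#'
#' @param counts [count-table] with final-day invader and resident counts.
#' @param day4_reference [count-table] of day-4 resident densities from the
#'   sacrifice replicates (uninvaded).
#' @param schedules named list of [invasion_schedule()] per invader type;
#'   defaults to the standard SM and WS schedules.
#' @param mortality a [mortality_model()].
#' @param offset_mode `"density"` (default) applies the +1 cfu/ml offset to
#'   the final invader density before forming `x2`; `"none"` skips it (the
#'   alternative reading, under which the +1 enters only through the
#'   `log(v + 1)` transform itself).
#' @param final_day sampling day for `x2` (default 16).
#' @return a tibble of class `fitness_table`: one row per invaded microcosm
#'   with treatment columns, `resident_final`, `invader_final`, `x1`, `x2`,
#'   `v`, `log_v_plus_1`, `increased`.
#' @export
compute_fitness_table <- function(counts, day4_reference,
                                  schedules = list(
                                    SM = invasion_schedule("SM"),
                                    WS = invasion_schedule("WS")
                                  ),
                                  mortality = mortality_model(),
                                  offset_mode = c("density", "none"),
                                  final_day = 16) {
  offset_mode <- match.arg(offset_mode)

  final <- population_densities(counts, day = final_day) |>
    tidyr::pivot_wider(
      names_from = "population", values_from = "density",
      values_fill = 0
    )
  if (!"invader" %in% names(final)) final$invader <- 0
  if (!"resident" %in% names(final)) final$resident <- 0

  invaded_ids <- unique(dplyr::filter(counts, !is.na(.data$invader_type))$microcosm_id)
  skipped <- setdiff(invaded_ids, final$microcosm_id)
  if (length(skipped) > 0) {
    warning(
      length(skipped), " microcosm(s) missing day-", final_day,
      " counts were skipped: ", paste(utils::head(skipped, 5), collapse = ", "),
      call. = FALSE
    )
  }
  final <- dplyr::filter(final, !is.na(.data$invader_type))

  ref <- population_densities(day4_reference, day = 4) |>
    dplyr::filter(.data$population == "resident") |>
    dplyr::group_by(.data$resource, .data$disturbance_interval) |>
    dplyr::summarise(measured_R4 = mean(.data$density), .groups = "drop")

  # interval 8/16 treatments take the 4-day treatment's day-4 reference
  lookup_R4 <- function(resource, interval) {
    ref_interval <- if (interval > 4) 4L else interval
    hit <- ref$measured_R4[
      ref$resource == resource & ref$disturbance_interval == ref_interval
    ]
    if (length(hit) != 1) {
      stop(
        "no day-4 reference for treatment cell (resource = ", resource,
        ", disturbance_interval = ", ref_interval, ")",
        call. = FALSE
      )
    }
    hit
  }

  cells <- dplyr::distinct(final, .data$resource, .data$disturbance_interval,
                           .data$invader_type)
  cells$x1 <- vapply(seq_len(nrow(cells)), function(i) {
    sched <- schedules[[cells$invader_type[i]]]
    if (is.null(sched)) {
      stop("no invasion schedule for invader type ", cells$invader_type[i],
           call. = FALSE)
    }
    series <- impute_resident_series(
      lookup_R4(cells$resource[i], cells$disturbance_interval[i]),
      cells$disturbance_interval[i],
      mortality = mortality,
      invasion_days = sched$invasion_days
    )
    initial_invader_proportion(sched, series)
  }, numeric(1))

  out <- final |>
    dplyr::rename(resident_final = "resident", invader_final = "invader") |>
    dplyr::left_join(
      cells, by = c("resource", "disturbance_interval", "invader_type")
    )

  inv_adj <- if (offset_mode == "density") {
    apply_zero_offset(out$invader_final)
  } else {
    out$invader_final
  }
  out$x2 <- inv_adj / (inv_adj + out$resident_final)
  out$v <- relative_fitness_v(out$x1, out$x2)
  score <- success_score(out$v)
  out$log_v_plus_1 <- score$log_v_plus_1
  out$increased <- score$increased

  n_undefined <- sum(is.na(out$v))
  if (n_undefined > 0) {
    message(n_undefined, " microcosm(s) with undefined v (invader fixation) flagged NA")
  }
  class(out) <- c("fitness_table", class(out))
  out
}

#' Write a fitness table to CSV
#'
#' @param x a `fitness_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fitness <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
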