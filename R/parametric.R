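#' Per-resource slope sets for the parametric generator
#'
#' The reported per-resource disturbance slopes of the success score (on the
#' events-per-16-days coding): SM 0.12 (high), -0.048 (medium), -0.089 (low);
#' WS -0.24 (high), -0.033 (medium), -0.076 (low). Useful as generating truth
#' for parameter-recovery simulations.
#'
#' @return a tibble with `resource`, `invader_type`, `slope`.
#' @export
reported_slope_set <- function() {
  tibble::tibble(
    resource = rep(RESOURCE_LEVELS, 2),
    invader_type = rep(INVADER_TYPES, each = 3),
    slope = c(-0.089, -0.048, 0.12, -0.076, -0.033, -0.24)
  )
}

#' Configuration of the parametric response generator
#'
#' Generates responses cell by cell as
#' `intercept + slope * disturbance (+ quad * disturbance^2) + noise`,
#' with known generating coefficients, for calibration and recovery tests.
#'
#' @param slope_by tibble with `resource`, `invader_type`, `slope` and
#'   optionally `intercept`, `quad`; defaults to [reported_slope_set()].
#' @param intercept default intercept where `slope_by` has none.
#' @param residual_sd Gaussian residual standard deviation (default 0.3).
#' @param replicates per treatment cell (default 6).
#' @param disturbance_coding must match the coding used at analysis time.
#' @param response name of the generated response column.
#' @return a list of class `parametric_config`.
#' @export
parametric_config <- function(slope_by = reported_slope_set(),
                              intercept = 1,
                              residual_sd = 0.3,
                              replicates = 6,
                              disturbance_coding = "events_per_16d",
                              response = "log_v_plus_1") {
  stopifnot(residual_sd >= 0, replicates >= 1)
  slope_by <- tibble::as_tibble(slope_by)
  if (!"intercept" %in% names(slope_by)) slope_by$intercept <- intercept
  if (!"quad" %in% names(slope_by)) slope_by$quad <- 0
  structure(
    list(
      slope_by = slope_by,
      residual_sd = residual_sd,
      replicates = replicates,
      disturbance_coding = disturbance_coding,
      response = response
    ),
    class = "parametric_config"
  )
}

#' A null (all-slopes-zero) parametric configuration
#'
#' @param residual_sd Gaussian residual sd.
#' @param replicates per cell.
#' @return a `parametric_config` whose linear and quadratic coefficients are
#'   all zero.
#' @export
null_parametric_config <- function(residual_sd = 0.3, replicates = 6) {
  sb <- reported_slope_set()
  sb$slope <- 0
  parametric_config(slope_by = sb, residual_sd = residual_sd,
                    replicates = replicates)
}

#' Generate an analysis table from known coefficients
#'
#' One row per microcosm over the full 3 x 5 x (invader types present in
#' `slope_by`) x replicates design, with the response drawn from the linear
#' predictor plus Gaussian noise. The generating truth is attached as the
#' `"truth"` attribute.
#'
#' @param config a [parametric_config()].
#' @param seed integer seed.
#' @return a tibble with treatment columns, the coded `disturbance`, and the
#'   response column named by `config$response`.
#' @export
generate_parametric <- function(config = parametric_config(), seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    dplyr::distinct(config$slope_by, .data$resource, .data$invader_type),
    disturbance_interval = DISTURBANCE_INTERVALS,
    replicate = seq_len(config$replicates)
  )
  grid$disturbance <- code_disturbance(
    grid$disturbance_interval, config$disturbance_coding
  )
  grid <- dplyr::left_join(
    grid, config$slope_by, by = c("resource", "invader_type")
  )
  mu <- grid$intercept + grid$slope * grid$disturbance +
    grid$quad * grid$disturbance^2
  grid[[config$response]] <- mu + rnorm(nrow(grid), 0, config$residual_sd)
  grid$microcosm_id <- paste0(
    grid$resource, "_d", grid$disturbance_interval, "_",
    grid$invader_type, "_r", grid$replicate
  )
  out <- grid[, c(
    "microcosm_id", "resource", "disturbance_interval", "invader_type",
    "replicate", "disturbance", config$response
  )]
  attr(out, "truth") <- config$slope_by
  out
}
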