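#' Simpson's diversity index over morphotype classes
#'
#' `D = 1 - sum(p_i^2)` where `p_i` is the proportion of the i-th resident
#' morphotype (SM, WS or FS). Invader records must be excluded upstream.
#' Unobserved classes contribute `p = 0`, so `D` ranges from 0 (monoculture)
#' to `1 - 1/3` for three equally abundant morphotypes. `D` is invariant to
#' common rescaling, so raw colony counts and volume-standardised densities
#' give the same value.
#'
#' @param counts_by_morph named non-negative numeric vector (names among
#'   SM/WS/FS) of counts or densities.
#' @return a list of class `diversity_result` with `proportions`,
#'   `simpson_D`, `n_morphs` (number of observed, i.e. positive, classes).
#' @examples
#' simpson_index(c(SM = 1, WS = 1, FS = 1))$simpson_D # 2/3
#' @export
simpson_index <- function(counts_by_morph) {
  if (is.null(names(counts_by_morph)) ||
      !all(names(counts_by_morph) %in% MORPHOTYPES)) {
    stop("counts must be named with morphotypes among SM, WS, FS",
         call. = FALSE)
  }
  if (any(counts_by_morph < 0)) stop("counts must be non-negative", call. = FALSE)
  full <- setNames(numeric(length(MORPHOTYPES)), MORPHOTYPES)
  full[names(counts_by_morph)] <- full[names(counts_by_morph)] + counts_by_morph
  total <- sum(full)
  if (total == 0) {
    stop("undefined diversity: all morphotype counts are zero", call. = FALSE)
  }
  p <- full / total
  structure(
    list(
      proportions = p,
      simpson_D = 1 - sum(p^2),
      n_morphs = sum(full > 0)
    ),
    class = "diversity_result"
  )
}

#' Log-scaled total density
#'
#' `log10(total + 1)`, the scale used for the resident-density response.
#'
#' @param total_cfu_per_ml non-negative density.
#' @return `log10(total_cfu_per_ml + 1)`, vectorised.
#' @export
log_density <- function(total_cfu_per_ml) {
  if (any(total_cfu_per_ml < 0, na.rm = TRUE)) {
    stop("density must be non-negative", call. = FALSE)
  }
  log10(total_cfu_per_ml + 1)
}

#' Per-microcosm resident community summaries
#'
#' Simpson's diversity over the resident SM/WS/FS morphotypes (invader
#' excluded) and the log10-scaled total resident density, one row per
#' microcosm on the given day, joined to treatment columns. Microcosms where
#' no resident colony was counted get `simpson_D = NA` (diversity undefined)
#' and `log10_density = 0`; downstream models exclude NA rows listwise.
#'
#' @param counts a [count-table].
#' @param day sampling day (default 16).
#' @return a tibble with `simpson_D`, `total_cfu_per_ml`, `log10_density`.
#' @export
community_table <- function(counts, day = 16) {
  res <- population_densities(counts, day = day, by_morphotype = TRUE) |>
    dplyr::filter(.data$population == "resident")
  res |>
    dplyr::group_by(
      .data$microcosm_id, .data$resource, .data$disturbance_interval,
      .data$invader_type, .data$replicate
    ) |>
    dplyr::summarise(
      simpson_D = if (sum(.data$density) > 0) {
        simpson_index(setNames(.data$density, .data$morphotype))$simpson_D
      } else {
        NA_real_
      },
      total_cfu_per_ml = sum(.data$density),
      .groups = "drop"
    ) |>
    dplyr::mutate(log10_density = log_density(.data$total_cfu_per_ml))
}
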