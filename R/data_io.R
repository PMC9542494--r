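#' @name count-table
#' @title Tidy plate-count tables
#'
#' @description
#' The canonical interchange format is a tidy CSV with one row per plating
#' observation: which microcosm, which day, which treatment, whether the
#' colonies belong to the resident or the invader population, which
#' morphotype (SM, WS or FS), how many colonies, and at what dilution and
#' plated volume. Densities are always computed on demand with
#' [cfu_per_ml()], never stored in the file.
#'
#' Required columns (names are fixed):
#' `microcosm_id`, `day`, `resource`, `disturbance_interval`,
#' `invader_type`, `replicate`, `population`, `morphotype`,
#' `colony_count`, `dilution`, `plated_volume_ml`.
#'
#' `invader_type` may be `NA` for uninvaded (reference) microcosms.
NULL

count_columns <- function() {
  c(
    "microcosm_id", "day", "resource", "disturbance_interval",
    "invader_type", "replicate", "population", "morphotype",
    "colony_count", "dilution", "plated_volume_ml"
  )
}

treatment_columns <- function() {
  c("resource", "disturbance_interval", "invader_type", "replicate")
}

#' Construct and validate a count table
#'
#' @param x data frame with the columns listed in [count-table].
#' @param strict if `TRUE` (default) any invalid row aborts; if `FALSE`
#'   invalid rows are dropped with a warning giving their row numbers.
#' @param metadata optional named list attached as the `metadata` attribute.
#' @return a tibble of class `count_table`.
#' @export
as_count_table <- function(x, strict = TRUE, metadata = list()) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(count_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop(
      "count table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- dplyr::mutate(
    x,
    microcosm_id = as.character(.data$microcosm_id),
    day = as.integer(.data$day),
    resource = as.character(.data$resource),
    disturbance_interval = as.integer(.data$disturbance_interval),
    invader_type = as.character(.data$invader_type),
    replicate = as.integer(.data$replicate),
    population = as.character(.data$population),
    morphotype = as.character(.data$morphotype),
    colony_count = as.numeric(.data$colony_count),
    dilution = as.numeric(.data$dilution),
    plated_volume_ml = as.numeric(.data$plated_volume_ml)
  )

  bad <- !(
    !is.na(x$day) & x$day >= 0 & x$day <= 16 &
      x$resource %in% RESOURCE_LEVELS &
      x$disturbance_interval %in% DISTURBANCE_INTERVALS &
      (is.na(x$invader_type) | x$invader_type %in% INVADER_TYPES) &
      x$population %in% POPULATIONS &
      x$morphotype %in% MORPHOTYPES &
      !is.na(x$colony_count) & x$colony_count >= 0 &
      x$colony_count == floor(x$colony_count) &
      !is.na(x$dilution) & x$dilution > 0 & x$dilution <= 1 &
      !is.na(x$plated_volume_ml) & x$plated_volume_ml > 0
  )
  if (any(bad)) {
    msg <- paste0(
      sum(bad), " invalid row(s) at line(s): ",
      paste(utils::head(which(bad), 10), collapse = ", ")
    )
    if (strict) stop(msg, call. = FALSE)
    warning("dropping ", msg, call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }

  key <- paste(x$microcosm_id, x$day, x$population, x$morphotype, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop(
      "duplicate (microcosm_id, day, population, morphotype) combination(s), ",
      "first at row ", anyDuplicated(key),
      call. = FALSE
    )
  }
  n_treat <- dplyr::n_distinct(
    x[, c("microcosm_id", treatment_columns())]
  )
  if (n_treat != dplyr::n_distinct(x$microcosm_id)) {
    stop("records of one microcosm disagree on treatment fields", call. = FALSE)
  }

  class(x) <- c("count_table", class(x))
  attr(x, "metadata") <- metadata
  x
}

#' Read a tidy count CSV
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @param schema_strict abort on invalid rows (`TRUE`, default) or skip them
#'   with a warning (`FALSE`).
#' @param column_map optional named character vector mapping canonical column
#'   names to the names used in the file (adapter for externally deposited
#'   layouts), e.g. `c(colony_count = "count")`.
#' @return a [count-table] tibble.
#' @export
read_counts <- function(path, schema_strict = TRUE, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (column_map[[canon]] %in% names(x)) {
        names(x)[names(x) == column_map[[canon]]] <- canon
      }
    }
  }
  as_count_table(x, strict = schema_strict, metadata = list(source = path))
}

#' Write a count table to CSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` returns a
#' table equal to `x`.
#'
#' @param x a [count-table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  readr::write_csv(x[, count_columns()], path, progress = FALSE)
  invisible(path)
}

#' Colony-forming units per ml from a plate count
#'
#' Standard plating arithmetic: `colony_count / (dilution * plated_volume_ml)`.
#' Vectorised; zero counts map to zero density.
#'
#' @param colony_count non-negative number of colonies.
#' @param dilution fraction of the culture concentration plated, in `(0, 1]`.
#' @param plated_volume_ml volume spread on the plate, in ml.
#' @return density in cfu/ml.
#' @examples
#' cfu_per_ml(60, 1e-6, 0.06) # 1e9
#' @export
cfu_per_ml <- function(colony_count, dilution, plated_volume_ml) {
  if (any(colony_count < 0, na.rm = TRUE)) {
    stop("colony_count must be non-negative", call. = FALSE)
  }
  if (any(dilution <= 0, na.rm = TRUE) || any(plated_volume_ml <= 0, na.rm = TRUE)) {
    stop("dilution and plated_volume_ml must be positive", call. = FALSE)
  }
  colony_count / (dilution * plated_volume_ml)
}

#' Summarise the experimental design of a count table
#'
#' Counts distinct microcosms per treatment cell against the full factorial
#' grid of the observed factor levels, and flags empty cells. Reports, never
#' rejects; the table is not modified.
#'
#' @param x a [count-table].
#' @param expected_replicates optional integer; cells whose replicate count
#'   differs are listed in `deviating_cells`.
#' @return a list of class `design_summary` with elements
#'   `n_resource_levels`, `n_disturbance_levels`, `n_invader_types`,
#'   `replicates_per_cell` (tibble), `n_microcosms`, `missing_cells`,
#'   `deviating_cells`.
#' @export
validate_design <- function(x, expected_replicates = NULL) {
  stopifnot(nrow(x) > 0)
  has_invader <- any(!is.na(x$invader_type))
  cell_vars <- c("resource", "disturbance_interval",
                 if (has_invader) "invader_type")

  cells <- x |>
    dplyr::distinct(.data$microcosm_id, dplyr::pick(dplyr::all_of(cell_vars))) |>
    dplyr::count(dplyr::pick(dplyr::all_of(cell_vars)), name = "n_replicates")

  grid_levels <- list(
    resource = intersect(RESOURCE_LEVELS, unique(x$resource)),
    disturbance_interval = intersect(
      DISTURBANCE_INTERVALS, unique(x$disturbance_interval)
    )
  )
  if (has_invader) {
    grid_levels$invader_type <- intersect(
      INVADER_TYPES, unique(x$invader_type)
    )
  }
  grid <- tidyr::expand_grid(!!!grid_levels)
  cells <- dplyr::left_join(grid, cells, by = cell_vars) |>
    dplyr::mutate(n_replicates = dplyr::coalesce(.data$n_replicates, 0L))

  missing_cells <- dplyr::filter(cells, .data$n_replicates == 0L)
  deviating <- if (is.null(expected_replicates)) {
    dplyr::filter(cells, .data$n_replicates != stats::median(cells$n_replicates))
  } else {
    dplyr::filter(cells, .data$n_replicates != expected_replicates)
  }

  structure(
    list(
      n_resource_levels = length(grid_levels$resource),
      n_disturbance_levels = length(grid_levels$disturbance_interval),
      n_invader_types = if (has_invader) length(grid_levels$invader_type) else 0L,
      replicates_per_cell = cells,
      n_microcosms = sum(cells$n_replicates),
      missing_cells = missing_cells,
      deviating_cells = deviating
    ),
    class = "design_summary"
  )
}

#' @export
print.design_summary <- function(x, ...) {
  cat(
    "Design:", x$n_resource_levels, "resource level(s) x",
    x$n_disturbance_levels, "disturbance interval(s)",
    if (x$n_invader_types > 0) paste("x", x$n_invader_types, "invader type(s)"),
    "\n"
  )
  cat("Microcosms:", x$n_microcosms, "\n")
  if (nrow(x$missing_cells) > 0) {
    cat("Missing cells:", nrow(x$missing_cells), "\n")
  } else {
    cat("No missing cells\n")
  }
  invisible(x)
}

#' Per-microcosm population densities on one day
#'
#' Sums cfu/ml over morphotypes within each (microcosm, population) and
#' returns one row per microcosm with resident and invader totals, keeping
#' treatment columns. Morphotype-resolved densities are available via
#' `by_morphotype = TRUE`.
#'
#' @param x a [count-table].
#' @param day which sampling day to extract (default 16, the final day).
#' @param by_morphotype keep the morphotype resolution instead of pooling.
#' @return a tibble.
#' @export
population_densities <- function(x, day = 16, by_morphotype = FALSE) {
  d <- dplyr::filter(x, .data$day == !!day)
  d <- dplyr::mutate(
    d,
    density = cfu_per_ml(.data$colony_count, .data$dilution, .data$plated_volume_ml)
  )
  group_vars <- c(
    "microcosm_id", treatment_columns(), "population",
    if (by_morphotype) "morphotype"
  )
  d |>
    dplyr::group_by(dplyr::pick(dplyr::all_of(group_vars))) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
}
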