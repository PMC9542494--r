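# builders for small in-code fixtures shared across test files

count_row <- function(microcosm_id = "m1", day = 16, resource = "high",
                      disturbance_interval = 2L, invader_type = "SM",
                      replicate = 1L, population = "resident",
                      morphotype = "SM", colony_count = 60,
                      dilution = 1e-6, plated_volume_ml = 0.06) {
  tibble::tibble(
    microcosm_id = microcosm_id, day = day, resource = resource,
    disturbance_interval = disturbance_interval, invader_type = invader_type,
    replicate = replicate, population = population, morphotype = morphotype,
    colony_count = colony_count, dilution = dilution,
    plated_volume_ml = plated_volume_ml
  )
}

# one invaded microcosm (resident 1e9, invader 5e8 cfu/ml at day 16) plus a
# day-4 reference microcosm (resident 5e7 cfu/ml) in the same treatment cell
oracle_fixture <- function() {
  counts <- as_count_table(dplyr::bind_rows(
    count_row(population = "resident", colony_count = 60),   # 1e9
    count_row(population = "invader", colony_count = 30)     # 5e8
  ))
  day4 <- as_count_table(
    count_row(
      microcosm_id = "r1", day = 4, invader_type = NA_character_,
      colony_count = 30, dilution = 1e-5                      # 5e7
    )
  )
  list(counts = counts, day4 = day4)
}

# a full-factorial single-replicate design table (one plating row per
# microcosm), used for design validation tests
design_table <- function(replicates = 1, drop_cell = NULL) {
  grid <- tidyr::expand_grid(
    resource = c("low", "medium", "high"),
    disturbance_interval = c(1L, 2L, 4L, 8L, 16L),
    invader_type = c("SM", "WS"),
    replicate = seq_len(replicates)
  )
  if (!is.null(drop_cell)) {
    grid <- dplyr::anti_join(grid, drop_cell,
                             by = intersect(names(grid), names(drop_cell)))
  }
  grid$microcosm_id <- paste0(
    grid$resource, "_", grid$disturbance_interval, "_",
    grid$invader_type, "_", grid$replicate
  )
  as_count_table(dplyr::bind_cols(
    grid,
    day = 16L, population = "resident", morphotype = "SM",
    colony_count = 100, dilution = 1e-6, plated_volume_ml = 0.06
  ))
}
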