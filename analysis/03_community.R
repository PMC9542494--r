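#!/usr/bin/env Rscript
# Resident community responses: Simpson's diversity over the SM/WS/FS
# morphotypes (invader excluded) and log10 total resident density, per
# microcosm at day 16.

library(invasim)
suppressMessages(library(dplyr))

counts <- read_counts("results/counts_day16.csv")
community <- community_table(counts)
readr::write_csv(community, "results/community.csv")

cat("Mean Simpson diversity by resource x disturbance interval:\n")
community |>
  group_by(resource, disturbance_interval) |>
  summarise(D = mean(simpson_D, na.rm = TRUE), .groups = "drop") |>
  tidyr::pivot_wider(names_from = disturbance_interval, values_from = D) |>
  as.data.frame() |>
  print(digits = 2)

cat("\nMean log10 resident density:\n")
community |>
  group_by(resource, disturbance_interval) |>
  summarise(ld = mean(log10_density), .groups = "drop") |>
  tidyr::pivot_wider(names_from = disturbance_interval, values_from = ld) |>
  as.data.frame() |>
  print(digits = 3)
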