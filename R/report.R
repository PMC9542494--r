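summarise_fit <- function(fit, ss_type = "III") {
  list(
    formula = deparse(fit$spec$formula),
    n = fit$n,
    n_excluded = fit$n_excluded,
    coefficients = tibble::tibble(
      term = names(coef(fit$fit)),
      estimate = unname(coef(fit$fit)),
      se = unname(sqrt(diag(vcov(fit$fit))))
    ),
    anova = anova_table(fit, ss_type)
  )
}

anova_p <- function(anova_tab, term) {
  hit <- anova_tab$p_value[anova_tab$term == term]
  if (length(hit) == 1) hit else NA_real_
}

#' Run the full invasion analysis battery
#'
#' Executes the analysis sequence on a validated count table:
#'
#' 1. per-microcosm fitness table ([compute_fitness_table()]) and resident
#'    community summaries ([community_table()]);
#' 2. the three-way success model `log(v+1) ~ disturbance * resource *
#'    invader_type` (disturbance linear) with a type III ANOVA;
#' 3. if the three-way interaction is significant at `alpha`, separate
#'    per-morphotype models `log(v+1) ~ disturbance * resource`, each with
#'    ANOVA, per-resource slopes with confidence intervals, and
#'    Bonferroni-adjusted resource comparisons;
#' 4. per-morphotype diversity models (quadratic disturbance crossed with
#'    resource, reduced by likelihood-ratio selection) and density models
#'    (same structure, response `log10(total + 1)`);
#' 5. per-morphotype resident-effects models: success on
#'    `simpson_D * log10_density` alone, then treatments plus resident
#'    effects, tested with type III sums of squares and re-tested with type
#'    II when no interaction is significant at `alpha`.
#'
#' @param counts [count-table] of final-day counts for the invaded design.
#' @param day4_reference [count-table] of day-4 sacrifice-replicate counts.
#' @param alpha significance gate for branching and selection (default 0.05).
#' @param disturbance_coding see [code_disturbance()].
#' @param offset_mode zero-inflation handling, see [compute_fitness_table()].
#' @param schedules per-invader [invasion_schedule()]s.
#' @param mortality a [mortality_model()].
#' @return a list of class `invasion_report` (nested per-model summaries,
#'   plus the `fitness` and `community` tables and the analysis `data`).
#' @export
run_invasion_analysis <- function(counts, day4_reference,
                                  alpha = 0.05,
                                  disturbance_coding = "events_per_16d",
                                  offset_mode = "density",
                                  schedules = list(
                                    SM = invasion_schedule("SM"),
                                    WS = invasion_schedule("WS")
                                  ),
                                  mortality = mortality_model()) {
  fitness <- compute_fitness_table(
    counts, day4_reference,
    schedules = schedules, mortality = mortality, offset_mode = offset_mode
  )
  community <- community_table(counts)
  dat <- dplyr::left_join(
    fitness,
    community[, c("microcosm_id", "simpson_D", "total_cfu_per_ml",
                  "log10_density")],
    by = "microcosm_id"
  )

  report <- list(
    alpha = alpha,
    disturbance_coding = disturbance_coding,
    n_microcosms = dplyr::n_distinct(dat$microcosm_id),
    n_undefined_v = sum(is.na(dat$v))
  )

  # (2) three-way success model
  spec3 <- model_spec(
    "log_v_plus_1", disturbance_degree = 1,
    disturbance_coding = disturbance_coding,
    factors = c("resource", "invader_type")
  )
  fit3 <- fit_linear_model(spec3, dat)
  an3 <- anova_table(fit3, "III")
  p3way <- anova_p(an3, "disturbance:resource:invader_type")
  report$success_three_way <- c(
    summarise_fit(fit3, "III"),
    list(three_way_p = p3way, three_way_significant = isTRUE(p3way < alpha))
  )

  per_morph <- function(morph) {
    sub <- function(d) d[d$invader_type == morph, , drop = FALSE]
    out <- list()

    if (isTRUE(p3way < alpha)) {
      spec_s <- model_spec(
        "log_v_plus_1", disturbance_degree = 1,
        disturbance_coding = disturbance_coding,
        factors = "resource", data_filter = sub
      )
      fit_s <- fit_linear_model(spec_s, dat)
      out$success <- c(
        summarise_fit(fit_s, "III"),
        list(
          slopes = resource_specific_slopes(fit_s),
          posthoc_resource = marginal_pairwise(fit_s, "resource")
        )
      )
    }

    for (resp in c("simpson_D", "log10_density")) {
      spec_r <- model_spec(
        resp, disturbance_degree = 2,
        disturbance_coding = disturbance_coding,
        factors = "resource", data_filter = sub
      )
      sel <- likelihood_ratio_select(spec_r, dat, alpha = alpha)
      labels <- attr(terms(sel$fit$fit), "term.labels")
      has_int <- any(grepl(":", labels, fixed = TRUE))
      entry <- c(
        summarise_fit(sel$fit, if (has_int) "III" else "II"),
        list(selection_trace = sel$trace)
      )
      if ("resource" %in% labels) {
        entry$posthoc_resource <- marginal_pairwise(sel$fit, "resource")
      }
      nm <- if (resp == "simpson_D") "diversity" else "density"
      out[[nm]] <- entry
    }

    # resident effects alone
    spec_res <- model_spec(
      "log_v_plus_1",
      formula = log_v_plus_1 ~ simpson_D * log10_density,
      data_filter = sub
    )
    fit_res <- fit_linear_model(spec_res, dat)
    an_res3 <- anova_table(fit_res, "III")
    int_p <- anova_p(an_res3, "simpson_D:log10_density")
    out$resident_effects <- c(
      summarise_fit(fit_res, "III"),
      if (!isTRUE(int_p < alpha)) list(anova_type_II = anova_table(fit_res, "II"))
    )

    # treatments + resident effects
    spec_both <- model_spec(
      "log_v_plus_1", disturbance_degree = 1,
      disturbance_coding = disturbance_coding,
      factors = "resource",
      covariates = c("simpson_D", "log10_density"),
      data_filter = sub
    )
    fit_both <- fit_linear_model(spec_both, dat)
    an_both3 <- anova_table(fit_both, "III")
    int_p2 <- anova_p(an_both3, "disturbance:resource")
    out$treatments_plus_residents <- c(
      summarise_fit(fit_both, "III"),
      list(interaction_p = int_p2),
      if (!isTRUE(int_p2 < alpha)) {
        list(anova_type_II = anova_table(fit_both, "II"))
      }
    )
    out
  }

  report$SM <- per_morph("SM")
  report$WS <- per_morph("WS")
  report$fitness <- fitness
  report$community <- community
  report$data <- dat
  class(report) <- c("invasion_report", "list")
  report
}

#' @export
print.invasion_report <- function(x, ...) {
  cat("Invasion analysis report (", x$n_microcosms, "microcosms,",
      x$n_undefined_v, "undefined v )\n")
  cat(
    "Three-way disturbance x resource x invader interaction: p =",
    format(x$success_three_way$three_way_p, digits = 3),
    if (x$success_three_way$three_way_significant) "(significant)\n" else "(ns)\n"
  )
  for (m in INVADER_TYPES) {
    if (!is.null(x[[m]]$success)) {
      cat("\n", m, "invader per-resource disturbance slopes:\n")
      print(as.data.frame(x[[m]]$success$slopes), row.names = FALSE)
    }
  }
  invisible(x)
}

#' Serialise an invasion report to JSON
#'
#' Tables become arrays of row objects; the raw per-microcosm `data` table is
#' included so a report round-trips losslessly enough for archival.
#'
#' @param report an `invasion_report`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- unclass(report)
  js <- jsonlite::toJSON(
    payload, dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (is.null(path)) {
    return(as.character(js))
  }
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read back a JSON invasion report
#'
#' @param path path written by [report_to_json()].
#' @return a nested list (tables as data frames).
#' @export
report_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
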