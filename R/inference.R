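#' Numeric coding of disturbance frequency
#'
#' The models treat disturbance as a continuous predictor. The default coding
#' is the number of disturbance events over the 16-day experiment
#' (`events_per_16d`: intervals 1/2/4/8/16 days map to 16/8/4/2/1 events), so
#' that larger values mean more disturbance and "greater disturbance
#' increased success" corresponds to a positive slope. Alternatives:
#' the raw interval in days (`interval_days`) and `log2` of the event count
#' (`log2_events`).
#'
#' @param disturbance_interval integer days between disturbances.
#' @param coding one of `"events_per_16d"`, `"interval_days"`, `"log2_events"`.
#' @return numeric vector.
#' @export
code_disturbance <- function(disturbance_interval,
                             coding = c("events_per_16d", "interval_days",
                                        "log2_events")) {
  coding <- match.arg(coding)
  if (any(disturbance_interval <= 0)) {
    stop("disturbance_interval must be positive", call. = FALSE)
  }
  events <- floor(16 / disturbance_interval)
  switch(coding,
    events_per_16d = events,
    interval_days = as.numeric(disturbance_interval),
    log2_events = log2(events)
  )
}

#' Specify a linear model of the analysis battery
#'
#' Builds the model formula from its parts: a continuous disturbance term
#' (optionally quadratic), categorical treatment factors, and additive
#' continuous covariates. With `interactions = "all"` the disturbance terms
#' and factors are fully crossed; covariates always enter additively. A
#' ready-made `formula` overrides the constructed one (used e.g. for the
#' resident-effects model `log_v_plus_1 ~ simpson_D * log10_density`).
#'
#' @param response one of `"log_v_plus_1"`, `"simpson_D"`, `"log10_density"`,
#'   or any column name of the analysis table.
#' @param disturbance_degree 0 (no disturbance term), 1 (linear, the default
#'   for success models) or 2 (adds `I(disturbance^2)`, the default for
#'   diversity/density models).
#' @param disturbance_coding see [code_disturbance()].
#' @param factors character subset of `c("resource", "invader_type")`.
#' @param covariates character vector of additive continuous predictors.
#' @param interactions `"all"` (cross disturbance terms with factors) or
#'   `"none"`.
#' @param data_filter optional function applied to the data before fitting
#'   (e.g. `function(d) d[d$invader_type == "SM", ]`).
#' @param formula optional explicit formula overriding the constructed one.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(response,
                       disturbance_degree = 1,
                       disturbance_coding = "events_per_16d",
                       factors = character(),
                       covariates = character(),
                       interactions = c("all", "none"),
                       data_filter = NULL,
                       formula = NULL) {
  interactions <- match.arg(interactions)
  stopifnot(disturbance_degree %in% 0:2)
  if (is.null(formula)) {
    dist_terms <- switch(as.character(disturbance_degree),
      "0" = character(),
      "1" = "disturbance",
      "2" = c("disturbance", "I(disturbance^2)")
    )
    core <- if (interactions == "all" && length(dist_terms) > 0 &&
                length(factors) > 0) {
      paste0(
        "(", paste(dist_terms, collapse = " + "), ") * ",
        paste(factors, collapse = " * ")
      )
    } else if (interactions == "all" && length(factors) > 1) {
      paste(factors, collapse = " * ")
    } else {
      paste(c(dist_terms, factors), collapse = " + ")
    }
    rhs <- paste(c(core, covariates), collapse = " + ")
    if (rhs == "") rhs <- "1"
    formula <- stats::as.formula(paste(response, "~", rhs))
  }
  structure(
    list(
      response = response,
      disturbance_degree = disturbance_degree,
      disturbance_coding = disturbance_coding,
      factors = factors,
      covariates = covariates,
      interactions = interactions,
      data_filter = data_filter,
      formula = formula
    ),
    class = "model_spec"
  )
}

prepare_model_data <- function(spec, data) {
  d <- tibble::as_tibble(data)
  if (!is.null(spec$data_filter)) d <- spec$data_filter(d)
  if ("disturbance_interval" %in% names(d)) {
    d$disturbance <- code_disturbance(
      d$disturbance_interval, spec$disturbance_coding
    )
  }
  if ("resource" %in% names(d)) {
    d$resource <- droplevels(factor(d$resource, levels = RESOURCE_LEVELS))
  }
  if ("invader_type" %in% names(d)) {
    d$invader_type <- droplevels(factor(d$invader_type, levels = INVADER_TYPES))
  }
  keep <- !is.na(d[[spec$response]])
  attr_excluded <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  attr(d, "n_excluded") <- attr_excluded
  d
}

#' Fit an OLS linear model from a model specification
#'
#' Ordinary least squares via [stats::lm()], with treatment contrasts and
#' `low` as the resource reference level. Rows with an undefined (NA)
#' response are excluded listwise; the count of exclusions is recorded.
#'
#' @param spec a [model_spec()].
#' @param data analysis table (needs `disturbance_interval` plus the model's
#'   variables).
#' @return a list of class `inv_fit`: `fit` (the `lm`), `spec`, `data` (the
#'   prepared model data), `n`, `n_excluded`.
#' @export
fit_linear_model <- function(spec, data) {
  d <- prepare_model_data(spec, data)
  if ("disturbance" %in% all.vars(spec$formula) &&
      dplyr::n_distinct(d$disturbance) < 2) {
    stop("need at least 2 distinct disturbance values", call. = FALSE)
  }
  fit <- stats::lm(spec$formula, data = d)
  if (any(is.na(coef(fit)))) {
    stop(
      "rank-deficient design; aliased term(s): ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      fit = fit,
      spec = spec,
      data = d,
      n = nrow(d),
      n_excluded = attr(d, "n_excluded")
    ),
    class = "inv_fit"
  )
}

#' @export
print.inv_fit <- function(x, ...) {
  cat("Linear model:", deparse(x$spec$formula), "\n")
  cat("n =", x$n, "(", x$n_excluded, "row(s) with undefined response excluded )\n")
  print(coef(x$fit))
  invisible(x)
}

#' ANOVA table with type II or type III sums of squares
#'
#' Type III tests each term adjusted for all others including its own
#' interactions (the model is refit internally with sum-to-zero contrasts,
#' which type III requires to be meaningful); type II respects marginality
#' and is used once no significant interactions remain. Both delegate to
#' [car::Anova()].
#'
#' @param x an `inv_fit`.
#' @param ss_type `"III"` or `"II"`.
#' @return a tibble with `term`, `sumsq`, `df`, `statistic`, `p_value`, plus
#'   a `Residuals` row carrying the residual df.
#' @export
anova_table <- function(x, ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  fit <- x$fit
  if (ss_type == "III") {
    fac <- names(Filter(is.factor, x$data[all.vars(x$spec$formula)]))
    contr <- lapply(setNames(fac, fac), function(nm) stats::contr.sum)
    fit <- stats::lm(x$spec$formula, data = x$data, contrasts = contr)
    tab <- car::Anova(fit, type = 3)
    tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]
  } else {
    tab <- car::Anova(fit, type = 2)
  }
  tibble::tibble(
    term = rownames(tab),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
}

#' Likelihood-ratio test between two nested OLS fits
#'
#' For Gaussian OLS the likelihood-ratio statistic has the closed form
#' `n * ln(RSS_reduced / RSS_full)`, compared to a chi-squared distribution
#' with degrees of freedom equal to the difference in parameter counts.
#'
#' @param full,reduced `inv_fit` objects (or `lm` fits) on the same data;
#'   `reduced`'s terms must be a subset of `full`'s.
#' @return a one-row tibble with `statistic`, `df`, `p_value`, `rss_full`,
#'   `rss_reduced`.
#' @export
lrt <- function(full, reduced) {
  f <- if (inherits(full, "inv_fit")) full$fit else full
  r <- if (inherits(reduced, "inv_fit")) reduced$fit else reduced
  tf <- attr(terms(f), "term.labels")
  tr <- attr(terms(r), "term.labels")
  if (!all(tr %in% tf)) {
    stop("models are not nested: reduced model has terms absent from the full model",
         call. = FALSE)
  }
  n <- length(stats::residuals(f))
  if (n != length(stats::residuals(r))) {
    stop("models fit to different numbers of observations", call. = FALSE)
  }
  rss_f <- sum(stats::residuals(f)^2)
  rss_r <- sum(stats::residuals(r)^2)
  df <- df.residual(r) - df.residual(f)
  stat <- n * log(rss_r / rss_f)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(
    statistic = stat, df = df, p_value = p,
    rss_full = rss_f, rss_reduced = rss_r
  )
}

# degree map of a term label, treating I(x^2) as degree 2 in x
term_degrees <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^I\\((.+)\\^2\\)$", p))[[1]]
    if (length(m) == 2) {
      v <- m[2]; deg <- 2
    } else {
      v <- p; deg <- 1
    }
    out[[v]] <- max(out[[v]] %||% 0, deg)
  }
  out
}

# is term a marginal to (i.e. contained in) term b?
is_marginal_term <- function(a, b) {
  if (a == b) return(FALSE)
  da <- term_degrees(a)
  db <- term_degrees(b)
  all(names(da) %in% names(db)) &&
    all(vapply(names(da), function(v) da[[v]] <= db[[v]], logical(1)))
}

droppable_terms <- function(labels) {
  labels[vapply(labels, function(a) {
    !any(vapply(labels, function(b) is_marginal_term(a, b), logical(1)))
  }, logical(1))]
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starting from the full model, iteratively removes the droppable term (one
#' whose removal respects marginality: no main effect leaves while its
#' interaction stays, and no linear disturbance term while the quadratic
#' stays) with the largest likelihood-ratio p-value, as long as that p-value
#' exceeds `alpha`. Every test is recorded in the selection trace.
#'
#' @param spec a [model_spec()] for the full model.
#' @param data analysis table.
#' @param alpha retention threshold (default 0.05).
#' @return a list with `fit` (final `inv_fit`) and `trace` (tibble of every
#'   LRT performed: `step`, `term`, `statistic`, `df`, `p_value`, `dropped`).
#' @export
likelihood_ratio_select <- function(spec, data, alpha = 0.05) {
  current <- fit_linear_model(spec, data)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    labels <- attr(terms(current$fit), "term.labels")
    cand <- droppable_terms(labels)
    if (length(cand) == 0) break
    tests <- lapply(cand, function(tm) {
      reduced_formula <- stats::update(
        current$spec$formula, paste(". ~ . -", tm)
      )
      rspec <- current$spec
      rspec$formula <- reduced_formula
      rfit <- fit_linear_model(rspec, data)
      cbind(term = tm, lrt(current, rfit)[, c("statistic", "df", "p_value")])
    })
    tests <- dplyr::bind_rows(tests)
    tests$step <- step
    worst <- which.max(tests$p_value)
    tests$dropped <- seq_len(nrow(tests)) == worst & tests$p_value > alpha
    trace[[step]] <- tests
    if (tests$p_value[worst] <= alpha) break
    rspec <- current$spec
    rspec$formula <- stats::update(
      current$spec$formula, paste(". ~ . -", tests$term[worst])
    )
    current <- fit_linear_model(rspec, data)
  }
  list(
    fit = current,
    trace = if (length(trace) > 0) {
      dplyr::bind_rows(trace)[, c("step", "term", "statistic", "df",
                                  "p_value", "dropped")]
    } else {
      tibble::tibble(
        step = integer(), term = character(), statistic = numeric(),
        df = numeric(), p_value = numeric(), dropped = logical()
      )
    }
  )
}

#' Per-resource disturbance slopes with confidence intervals
#'
#' The marginal slope of the response in the coded disturbance regressor at
#' each resource level, with a t-based Wald confidence interval; a slope is
#' flagged significant when its interval excludes zero. Only defined for
#' degree-1 (linear-disturbance) models; quadratic models need curvature
#' summaries instead. Delegates to [emmeans::emtrends()].
#'
#' @param x an `inv_fit` containing a disturbance term.
#' @param level confidence level (default 0.95).
#' @return a tibble with `resource`, `slope`, `ci_lo`, `ci_hi`,
#'   `significant`.
#' @export
resource_specific_slopes <- function(x, level = 0.95) {
  labels <- attr(terms(x$fit), "term.labels")
  if (any(grepl("I(disturbance^2)", labels, fixed = TRUE))) {
    stop(
      "slopes are only reported for linear-disturbance models; ",
      "summarise curvature for quadratic fits instead",
      call. = FALSE
    )
  }
  if (!"disturbance" %in% all.vars(x$spec$formula)) {
    stop("model has no disturbance term", call. = FALSE)
  }
  if ("resource" %in% all.vars(x$spec$formula)) {
    tr <- emmeans::emtrends(
      x$fit, ~resource, var = "disturbance",
      data = x$data, level = level
    )
    s <- as.data.frame(summary(tr, infer = c(TRUE, FALSE), level = level))
    out <- tibble::tibble(
      resource = as.character(s$resource),
      slope = s$disturbance.trend,
      ci_lo = s$lower.CL,
      ci_hi = s$upper.CL
    )
  } else {
    ci <- confint(x$fit, "disturbance", level = level)
    out <- tibble::tibble(
      resource = "all",
      slope = unname(coef(x$fit)["disturbance"]),
      ci_lo = ci[1, 1],
      ci_hi = ci[1, 2]
    )
  }
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  out
}

#' Bonferroni-adjusted marginal pairwise comparisons
#'
#' Estimated marginal means of a categorical model term (model predictions
#' averaged over the levels/values of all other predictors, via
#' [emmeans::emmeans()]), compared pairwise; p-values are Bonferroni
#' adjusted, `p_adjusted = min(1, m * p_raw)` over the `m` comparisons.
#'
#' @param x an `inv_fit`.
#' @param factor name of a categorical predictor in the model.
#' @param adjustment only `"bonferroni"` is offered.
#' @return a tibble with `level_a`, `level_b`, `estimate`, `se`, `df`,
#'   `p_raw`, `p_adjusted`, `method`.
#' @export
marginal_pairwise <- function(x, factor = "resource",
                              adjustment = "bonferroni") {
  adjustment <- match.arg(adjustment)
  if (!factor %in% all.vars(x$spec$formula) || !is.factor(x$data[[factor]])) {
    stop("'", factor, "' is not a categorical predictor of the model",
         call. = FALSE)
  }
  em <- emmeans::emmeans(x$fit, specs = factor, data = x$data)
  raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
  levels_ab <- strsplit(as.character(raw$contrast), " - ", fixed = TRUE)
  tibble::tibble(
    level_a = vapply(levels_ab, `[`, character(1), 1),
    level_b = vapply(levels_ab, `[`, character(1), 2),
    estimate = raw$estimate,
    se = raw$SE,
    df = raw$df,
    p_raw = raw$p.value,
    p_adjusted = adj$p.value,
    method = adjustment
  )
}
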