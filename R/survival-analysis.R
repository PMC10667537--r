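validate_surv <- function(time, event) {
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("Follow-up times must be finite and > 0 ",
         "(subjects with time 0 are rejected, not shifted).", call. = FALSE)
  }
  invisible(NULL)
}

#' Stratified discovery/test split
#'
#' Splits a cohort into discovery and test sets by stratified random
#' sampling on the event indicator, so the two sets carry (to rounding)
#' equal event proportions. Deterministic for a fixed seed; the caller's
#' RNG stream is left untouched.
#'
#' @param cohort data frame with an `event` column (logical or 0/1).
#' @param test_fraction fraction assigned to the test set, in (0, 1)
#'   (default 0.3).
#' @param seed integer seed.
#' @param strata optional column name to stratify on instead of `event`.
#' @return `cohort` with a `split_label` column (`"discovery"` /
#'   `"test"`).
#' @export
stratified_split <- function(cohort, test_fraction = 0.3, seed,
                             strata = "event") {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be strictly between 0 and 1.", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  s <- factor(cohort[[strata]])
  if (any(table(s) < 2)) {
    stop("Every stratum must contain at least 2 subjects.", call. = FALSE)
  }
  label <- rep("discovery", nrow(cohort))
  with_seed(seed, {
    for (lev in levels(s)) {
      idx <- which(s == lev)
      n_test <- round(length(idx) * test_fraction)
      label[sample(idx, n_test)] <- "test"
    }
  })
  dplyr::mutate(cohort, split_label = label)
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin tidy wrapper over [survival::survfit()] (standard risk-set
#' convention: subjects censored at an event time remain at risk at that
#' time).
#'
#' @param time positive follow-up times (months).
#' @param event event indicators (logical or 0/1).
#' @param group optional grouping vector for stratified curves.
#' @return tibble of class `km_estimate`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (plus `group` when given), with a `t = 0,
#'   S = 1` row per stratum.
#' @export
km_estimate <- function(time, event, group = NULL) {
  validate_surv(time, event)
  event <- as.integer(as.logical(event))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- tibble::tibble(
      time = c(0, fit$time),
      n_risk = c(fit$n, fit$n.risk),
      n_event = c(0, fit$n.event),
      n_censor = c(0, fit$n.censor),
      surv = c(1, fit$surv)
    )
  } else {
    g <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    lev <- sub("^g=", "", names(fit$strata))
    out <- tibble::tibble(
      group = rep(lev, fit$strata),
      time = fit$time,
      n_risk = fit$n.risk,
      n_event = fit$n.event,
      n_censor = fit$n.censor,
      surv = fit$surv
    )
    heads <- tibble::tibble(
      group = lev, time = 0, n_risk = as.numeric(table(g)[lev]),
      n_event = 0, n_censor = 0, surv = 1
    )
    out <- dplyr::arrange(dplyr::bind_rows(heads, out),
                          .data$group, .data$time)
  }
  class(out) <- c("km_estimate", class(out))
  out
}

#' Log-rank test between two (or more) groups
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance summed over distinct event times, via
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param group grouping vector; every level must be nonempty.
#' @return one-row tibble: `chi_square`, `df`, `p_value`, `n`,
#'   `n_events`. Zero total events yields `NA` statistics with a
#'   warning.
#' @export
logrank_test <- function(time, event, group) {
  validate_surv(time, event)
  g <- factor(group)
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stop("`group` must contain at least two nonempty groups.", call. = FALSE)
  }
  event <- as.integer(as.logical(event))
  if (sum(event) == 0) {
    warning("No events: log-rank statistic undefined.", call. = FALSE)
    return(tibble::tibble(chi_square = NA_real_, df = nlevels(g) - 1L,
                          p_value = NA_real_, n = length(time),
                          n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  tibble::tibble(
    chi_square = unname(sd$chisq),
    df = nlevels(g) - 1L,
    p_value = stats::pchisq(sd$chisq, nlevels(g) - 1L, lower.tail = FALSE),
    n = length(time),
    n_events = sum(event)
  )
}

#' Outcome-based optimal cut-point (X-tile-style)
#'
#' Emulates outcome-driven dichotomisation: the log-rank chi-square of
#' high-vs-low (`high` means value strictly greater than the cut) is
#' evaluated at every candidate cut and the maximising cut returned.
#' Because the statistic is maximally selected, the attached p-value is
#' optimistic; it is reported as `p_uncorrected` together with an
#' explicit caveat, and the intended protocol is to derive the cut on a
#' discovery set and validate it on untouched data.
#'
#' @param feature_values numeric feature (>= 2 distinct values).
#' @inheritParams km_estimate
#' @param grid_policy `"percentile"` (default: cuts at the 5th-95th
#'   percentiles in steps of 1) or `"unique"` (every observed value).
#' @param min_group_fraction both sides of an admissible cut must hold
#'   at least this fraction of subjects (default 0.1).
#' @param feature_name label carried into the result.
#' @return a `cutpoint_result`: `feature_name`, `cutoff`,
#'   `chi_square_at_cutoff`, `p_uncorrected`, `caveat`, `n_low`,
#'   `n_high`, `grid_policy`, `derived_on`.
#' @export
optimal_cutpoint <- function(feature_values, time, event,
                             grid_policy = c("percentile", "unique"),
                             min_group_fraction = 0.1,
                             feature_name = "feature") {
  grid_policy <- match.arg(grid_policy)
  validate_surv(time, event)
  if (length(unique(feature_values)) < 2) {
    stop("Feature must have at least 2 distinct values.", call. = FALSE)
  }
  n <- length(feature_values)
  candidates <- if (grid_policy == "percentile") {
    unique(stats::quantile(feature_values, probs = seq(0.05, 0.95, by = 0.01),
                           type = 7, names = FALSE))
  } else {
    sort(unique(feature_values))
  }
  min_n <- ceiling(min_group_fraction * n)
  n_high <- vapply(candidates, function(ct) sum(feature_values > ct),
                   numeric(1))
  ok <- n_high >= min_n & (n - n_high) >= min_n
  candidates <- candidates[ok]
  if (!length(candidates)) {
    stop("No candidate cut satisfies the minimum group-size constraint (",
         min_group_fraction, " of n on both sides).", call. = FALSE)
  }
  event <- as.integer(as.logical(event))
  chisq <- vapply(candidates, function(ct) {
    g <- feature_values > ct
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(sd$chisq)
  }, numeric(1))
  best <- which(chisq >= max(chisq) - 1e-12)
  if (length(best) > 1) {
    med <- stats::median(feature_values)
    best <- best[which.min(abs(candidates[best] - med))]
  }
  cutoff <- candidates[best]
  structure(list(
    feature_name = feature_name,
    cutoff = cutoff,
    chi_square_at_cutoff = chisq[best],
    p_uncorrected = stats::pchisq(chisq[best], 1, lower.tail = FALSE),
    caveat = paste("p_uncorrected is a maximally selected log-rank p-value;",
                   "it is optimistic and must be validated on held-out data."),
    n_low = sum(feature_values <= cutoff),
    n_high = sum(feature_values > cutoff),
    grid_policy = grid_policy,
    derived_on = "discovery",
    grid = tibble::tibble(cutoff = candidates, chi_square = chisq)
  ), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint_result> ", x$feature_name, ": cutoff = ", format(x$cutoff),
      " (chi-square ", format(x$chi_square_at_cutoff, digits = 4),
      ", n_low ", x$n_low, ", n_high ", x$n_high, ", grid ", x$grid_policy,
      ")\n  ", x$caveat, "\n", sep = "")
  invisible(x)
}

#' Tidy a cutpoint result
#' @param x a `cutpoint_result`.
#' @param ... unused.
#' @return one-row tibble (grid omitted).
#' @method tidy cutpoint_result
#' @export
tidy.cutpoint_result <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_name, cutoff = x$cutoff,
    chi_square = x$chi_square_at_cutoff, p_uncorrected = x$p_uncorrected,
    n_low = x$n_low, n_high = x$n_high, grid_policy = x$grid_policy,
    derived_on = x$derived_on, caveat = x$caveat
  )
}

#' Apply a previously derived cut-point
#'
#' `high` iff value strictly greater than `cutoff`; the cut derived on
#' the discovery set is reused unchanged on test/validation data.
#'
#' @param feature_values numeric vector.
#' @param cutoff finite cut value (or a `cutpoint_result`).
#' @return factor with levels `low`, `high`.
#' @export
apply_cutpoint <- function(feature_values, cutoff) {
  if (inherits(cutoff, "cutpoint_result")) cutoff <- cutoff$cutoff
  assert_scalar_number(cutoff, "cutoff")
  lab <- factor(ifelse(feature_values > cutoff, "high", "low"),
                levels = c("low", "high"))
  if (length(unique(lab)) < 2) {
    warning("Degenerate dichotomisation: all subjects fall on one side ",
            "of the cutoff.", call. = FALSE)
  }
  lab
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] (Efron tie handling by
#' default; Breslow available, under which the score test at beta = 0
#' for a single binary covariate equals the log-rank chi-square).
#' Hazard ratios are `exp(beta)` with 95% Wald confidence intervals from
#' the observed information.
#'
#' @param data data frame holding the covariates.
#' @param covariates character vector of covariate column names; one
#'   gives a univariate model, several a multivariate model.
#' @inheritParams km_estimate
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `cox_result`: the underlying fit plus a tidy per-covariate
#'   table (`term`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `n_events`, `model`).
#' @export
cox_fit <- function(data, covariates, time, event,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  validate_surv(time, event)
  event <- as.integer(as.logical(event))
  if (sum(event) < length(covariates)) {
    stop("Fewer events than covariates.", call. = FALSE)
  }
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("Covariate not found: ", cv, call. = FALSE)
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("Constant covariate: ", cv, call. = FALSE)
    }
  }
  df <- data[, covariates, drop = FALSE]
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (any(!is.finite(stats::coef(fit))) ||
      any(!is.finite(sqrt(diag(stats::vcov(fit)))))) {
    stop("Cox fit did not converge (possible monotone likelihood / ",
         "perfect separation).", call. = FALSE)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- tibble::tibble(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - stats::qnorm(0.975) * unname(se)),
    ci_high = exp(unname(beta) + stats::qnorm(0.975) * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    n = fit$n,
    n_events = fit$nevent,
    model = if (length(covariates) == 1) "cox_uni" else "cox_multi"
  )
  structure(list(fit = fit, table = tab, ties = ties,
                 covariates = covariates),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> ", x$table$model[1], " (", x$ties, " ties), n = ",
      x$table$n[1], ", events = ", x$table$n_events[1], "\n", sep = "")
  print(x$table[, c("term", "hr", "ci_low", "ci_high", "p_value")])
  invisible(x)
}

#' Tidy / glance methods for Cox results
#'
#' @param x a `cox_result`.
#' @param ... unused.
#' @return `tidy()`: the per-covariate table; `glance()`: one row with
#'   n, events, likelihood-ratio statistic, concordance.
#' @method tidy cox_result
#' @export
tidy.cox_result <- function(x, ...) x$table

#' @rdname tidy.cox_result
#' @method glance cox_result
#' @export
glance.cox_result <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$fit$n,
    n_events = x$fit$nevent,
    logtest_stat = unname(s$logtest["test"]),
    logtest_p = unname(s$logtest["pvalue"]),
    concordance = unname(s$concordance["C"]),
    ties = x$ties
  )
}

#' Rescale a log hazard to a per-k-units hazard ratio
#'
#' Cohort papers report count effects per 1000 units ("every 1000-unit
#' increase in tTILs count..."): `HR_k = exp(k * beta)`, with the CI
#' endpoints transformed identically.
#'
#' @param beta log hazard per raw unit; alternatively a `cox_result`
#'   (with `term` selecting the covariate).
#' @param k unit multiple (default 1000).
#' @param se optional standard error of `beta` for a 95% CI.
#' @param term covariate name when `beta` is a `cox_result`.
#' @return one-row tibble: `k`, `hr`, `ci_low`, `ci_high` (CIs `NA`
#'   without `se`).
#' @export
hr_per_k_units <- function(beta, k = 1000, se = NULL, term = NULL) {
  if (inherits(beta, "cox_result")) {
    tab <- beta$table
    row <- if (is.null(term)) 1L else match(term, tab$term)
    if (is.na(row)) stop("Term not found: ", term, call. = FALSE)
    se <- tab$se[row]
    beta <- tab$beta[row]
  }
  assert_scalar_number(beta, "beta")
  z <- stats::qnorm(0.975)
  tibble::tibble(
    k = k,
    hr = exp(k * beta),
    ci_low = if (is.null(se)) NA_real_ else exp(k * (beta - z * se)),
    ci_high = if (is.null(se)) NA_real_ else exp(k * (beta + z * se))
  )
}
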