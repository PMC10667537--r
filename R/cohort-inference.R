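#' Rank-based association tests with mean-rank reporting
#'
#' Cohort studies of TILs report, for each feature and each
#' clinicopathological grouping, the per-group mean rank of the feature
#' and a Mann-Whitney (2 groups) or Kruskal-Wallis (3+ groups) p-value.
#' These wrappers compute mid-ranks over the pooled data and report them
#' alongside the test.
#'
#' `mann_whitney()` reports the U statistic for the first group
#' (`U = R_a - n_a (n_a + 1) / 2` with mid-ranks). The two-sided p-value
#' comes from the tie-corrected normal approximation with continuity
#' correction (via [stats::wilcox.test()]); when the pooled sample size
#' is at most `exact_limit` the exact permutation distribution of U
#' (mid-ranks, so ties are handled) is enumerated instead.
#'
#' @param values_a,values_b numeric feature values of the two groups.
#' @param group_names length-2 labels used in the output.
#' @param correct apply continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param exact_limit enumerate the exact permutation p when
#'   `length(values_a) + length(values_b) <=` this (default 10); set to
#'   0 to force the approximation.
#' @return an `assoc_result`: list with `feature_name`, `grouping_name`,
#'   `groups` (tibble of `group`, `n`, `mean_rank`), `statistic`,
#'   `p_value`, `test`.
#' @export
mann_whitney <- function(values_a, values_b, group_names = c("a", "b"),
                         correct = TRUE, exact_limit = 10) {
  if (!length(values_a) || !length(values_b)) {
    stop("Both groups must be nonempty.", call. = FALSE)
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)  # mid-ranks
  r_a <- sum(rk[seq_len(n_a)])
  u <- r_a - n_a * (n_a + 1) / 2

  if (n_a + n_b <= exact_limit) {
    p <- exact_mw_p(rk, n_a)
  } else {
    tie_sum <- sum(table(pooled)^3 - table(pooled))
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(values_a, values_b, exact = FALSE,
                           correct = correct)$p.value
      )
      if (is.na(p)) p <- 1
    }
  }

  new_assoc_result(
    groups = tibble::tibble(
      group = group_names,
      n = c(n_a, n_b),
      mean_rank = c(r_a / n_a, (sum(rk) - r_a) / n_b)
    ),
    statistic = u, p_value = p, test = "mann_whitney"
  )
}

# exact two-sided permutation p for U with mid-ranks
exact_mw_p <- function(rk, n_a) {
  n <- length(rk)
  mu <- n_a * (n - n_a) / 2
  off <- n_a * (n_a + 1) / 2
  obs <- abs(sum(rk[seq_len(n_a)]) - off - mu)
  picks <- utils::combn(n, n_a)
  u_all <- colSums(matrix(rk[picks], nrow = n_a)) - off
  mean(abs(u_all - mu) >= obs - 1e-12)
}

new_assoc_result <- function(groups, statistic, p_value, test,
                             feature_name = NA_character_,
                             grouping_name = NA_character_) {
  structure(list(
    feature_name = feature_name, grouping_name = grouping_name,
    groups = groups, statistic = statistic, p_value = p_value, test = test
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", x$test, ": statistic = ",
      format(x$statistic), ", p = ", format.pval(x$p_value), "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Tidy an association result
#'
#' @param x an `assoc_result`.
#' @param ... unused.
#' @return tibble with one row per group plus the shared statistic/p.
#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) {
  dplyr::mutate(x$groups,
                statistic = x$statistic, p_value = x$p_value, test = x$test,
                feature = x$feature_name, grouping = x$grouping_name)
}

#' @rdname mann_whitney
#' @param groups list of numeric vectors (one per group); with exactly
#'   two groups the call delegates to `mann_whitney()`.
#' @export
kruskal_wallis <- function(groups, group_names = names(groups)) {
  if (any(lengths(groups) == 0)) {
    stop("All groups must be nonempty.", call. = FALSE)
  }
  if (is.null(group_names)) group_names <- as.character(seq_along(groups))
  if (length(groups) < 2) stop("Need at least 2 groups.", call. = FALSE)
  if (length(groups) == 2) {
    return(mann_whitney(groups[[1]], groups[[2]], group_names = group_names))
  }
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  rk <- rank(pooled)
  mean_ranks <- tapply(rk, g, mean)
  kt <- stats::kruskal.test(pooled, g)
  new_assoc_result(
    groups = tibble::tibble(
      group = group_names,
      n = lengths(groups),
      mean_rank = as.numeric(mean_ranks)
    ),
    statistic = unname(kt$statistic),
    p_value = if (is.na(kt$p.value)) 1 else kt$p.value,
    test = "kruskal_wallis"
  )
}

#' Correlation between two features
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row tibble with `r`, `p_value`, `method`, `n`. Zero
#'   variance in either vector yields `NA` with a warning (undefined).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("Need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Zero variance: correlation undefined.", call. = FALSE)
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          method = method, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}

#' Intraclass correlation for visual-vs-automated agreement
#'
#' Two-way random-effects model, absolute agreement, single measures
#' (the standard choice for method-agreement between two fixed raters,
#' e.g. a pathologist's visual sTILs percentage against the automated
#' one), computed from the mean-squares decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param rater1,rater2 paired numeric scores, equal length >= 3.
#' @return an `agreement_result`: list with `icc`, `model`,
#'   `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) {
    stop("Raters must score the same subjects.", call. = FALSE)
  }
  ok <- is.finite(rater1) & is.finite(rater2)
  rater1 <- rater1[ok]
  rater2 <- rater2[ok]
  n <- length(rater1)
  if (n < 3) stop("Need at least 3 paired scores.", call. = FALSE)
  k <- 2
  m <- cbind(rater1, rater2)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(row_means)  # balanced design: equals the grand mean
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  mse <- (sum((m - outer(row_means, rep(1, k)) -
                 outer(rep(1, n), col_means) + grand)^2)) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (msr <= .Machine$double.eps && denom <= .Machine$double.eps) {
    warning("No between-subject variance: ICC undefined.", call. = FALSE)
    icc <- NA_real_
  } else {
    icc <- (msr - mse) / denom
  }
  structure(list(icc = icc, model = "two_way_absolute_single",
                 n_subjects = n, n_raters = k),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ICC(", x$model, ") = ", format(x$icc),
      " [n = ", x$n_subjects, ", raters = ", x$n_raters, "]\n", sep = "")
  invisible(x)
}

#' Association battery over a cohort table
#'
#' For each feature x grouping pair, runs [mann_whitney()] (2 groups) or
#' [kruskal_wallis()] (3+), and returns the long table of per-group n,
#' mean rank and p-value that cohort papers print.
#'
#' @param cohort data frame with one row per patient.
#' @param features character vector of numeric feature columns.
#' @param groupings character vector of grouping columns (logical,
#'   factor or character; rows with missing grouping are dropped
#'   per-test).
#' @return long tibble: `feature`, `grouping`, `group`, `n`,
#'   `mean_rank`, `statistic`, `p_value`, `test`.
#' @export
association_battery <- function(cohort, features, groupings) {
  combos <- tidyr::expand_grid(feature = features, grouping = groupings)
  purrr::pmap_dfr(combos, function(feature, grouping) {
    v <- cohort[[feature]]
    g <- cohort[[grouping]]
    ok <- !is.na(v) & !is.na(g)
    v <- v[ok]
    g <- factor(g[ok])
    if (nlevels(g) < 2 || length(v) < 2) {
      return(tibble::tibble())
    }
    res <- kruskal_wallis(split(v, g), group_names = levels(g))
    res$feature_name <- feature
    res$grouping_name <- grouping
    tidy(res)[, c("feature", "grouping", "group", "n", "mean_rank",
                  "statistic", "p_value", "test")]
  })
}
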