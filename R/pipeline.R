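DEFAULT_FEATURES <- c("stils_count", "ttils_count", "total_tils",
                      "stils_pct", "stroma_immune_cooc",
                      "tumour_immune_cooc")

#' Run the full TILs prognostic-analysis protocol on a cohort
#'
#' Reproduces the standard protocol end to end: stratified
#' discovery/test split; for each TILs feature an outcome-based
#' cut-point derived on the discovery set only and applied unchanged to
#' the test set; Kaplan-Meier tables and log-rank tests for both sets;
#' univariate Cox models of high-vs-low; a multivariate Cox model of the
#' tTILs count (continuous, reported per 1000 units) adjusted for
#' grade, lymph-node status, Ki67 and tumour size; the association
#' battery of every feature against the clinicopathological variables;
#' a correlation panel; and (when visual scores are present) the
#' visual-vs-automated ICC.
#'
#' The test set is never touched during cut-point derivation: cut-point
#' calls receive only discovery rows, and the manifest records the
#' discovery row indices used as an audit trail. For a fixed config and
#' seed the written outputs are byte-identical across runs (no
#' timestamps are embedded).
#'
#' @param cohort data frame with one row per patient: `time_months`,
#'   `event`, the feature columns, and (for associations / the adjusted
#'   model) `grade`, `ln_positive`, `ki67_high`, `size_cm`,
#'   `age_years`; optionally `visual_stils_pct`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the stratified split.
#' @param features numeric feature columns to analyse.
#' @param test_fraction fraction of patients in the test set
#'   (default 0.3).
#' @param min_group_fraction minimum group fraction for admissible cuts.
#' @return invisibly, a list with every result table; files written:
#'   `manifest.json`, `cohort_with_features.csv`, `cutpoints.csv`,
#'   `survival_results.csv`, `associations.csv`, `correlations.csv`,
#'   `icc.csv`, `km_curves/<feature>_<set>.csv`.
#' @export
run_tils_pipeline <- function(cohort, out_dir, seed,
                              features = DEFAULT_FEATURES,
                              test_fraction = 0.3,
                              min_group_fraction = 0.1) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  features <- intersect(features, names(cohort))
  required <- c("time_months", "event", features)
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("Cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  km_dir <- file.path(out_dir, "km_curves")
  if (!dir.exists(km_dir)) dir.create(km_dir)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  cohort <- stratified_split(cohort, test_fraction = test_fraction,
                             seed = seed)
  disc <- dplyr::filter(cohort, .data$split_label == "discovery")
  test <- dplyr::filter(cohort, .data$split_label == "test")
  n_events <- sum(cohort$event)

  cutpoints <- tibble::tibble()
  surv_results <- tibble::tibble()
  if (n_events == 0) {
    note("no events: survival stages skipped")
    surv_results <- tibble::tibble(
      feature = features, set = "all", model = "none",
      note = "no events: survival analysis skipped"
    )
  } else {
    for (f in features) {
      cp <- optimal_cutpoint(disc[[f]], disc$time_months, disc$event,
                             min_group_fraction = min_group_fraction,
                             feature_name = f)
      cutpoints <- dplyr::bind_rows(cutpoints, tidy(cp))
      for (set_name in c("discovery", "test")) {
        d <- if (set_name == "discovery") disc else test
        grp <- apply_cutpoint(d[[f]], cp)
        if (length(unique(grp)) < 2) {
          note(f, "/", set_name, ": degenerate dichotomisation")
          next
        }
        lr <- logrank_test(d$time_months, d$event, grp)
        km <- km_estimate(d$time_months, d$event, grp)
        readr::write_csv(km, file.path(km_dir,
                                       paste0(f, "_", set_name, ".csv")),
                         progress = FALSE)
        dd <- dplyr::mutate(d, .grp = as.integer(grp == "high"))
        cx <- cox_fit(dd, ".grp", dd$time_months, dd$event)
        surv_results <- dplyr::bind_rows(
          surv_results,
          tibble::tibble(
            feature = f, set = set_name, model = "km_logrank",
            hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            statistic = lr$chi_square, p_value = lr$p_value,
            n = lr$n, n_events = lr$n_events
          ),
          dplyr::mutate(
            dplyr::select(tidy(cx), -"term", -"beta", -"se", -"model"),
            feature = f, set = set_name, model = "cox_uni_high_vs_low",
            statistic = NA_real_, .before = 1
          )
        )
      }
    }

    # multivariate: continuous tTILs adjusted for grade, LN, Ki67, size
    adj <- c("grade", "ln_positive", "ki67_high", "size_cm")
    if (all(c("ttils_count", adj) %in% names(cohort))) {
      for (set_name in c("discovery", "test")) {
        d <- if (set_name == "discovery") disc else test
        cx <- try(cox_fit(d, c("ttils_count", adj),
                          d$time_months, d$event), silent = TRUE)
        if (inherits(cx, "try-error")) {
          note("multivariate Cox failed on ", set_name, " set")
          next
        }
        per1000 <- hr_per_k_units(cx, k = 1000, term = "ttils_count")
        surv_results <- dplyr::bind_rows(
          surv_results,
          dplyr::mutate(dplyr::select(tidy(cx), -"beta", -"se", -"model"),
                        feature = .data$term, set = set_name,
                        model = "cox_multi", statistic = NA_real_,
                        .keep = "unused"),
          tibble::tibble(
            feature = "ttils_count_per_1000", set = set_name,
            model = "cox_multi_per_1000",
            hr = per1000$hr, ci_low = per1000$ci_low,
            ci_high = per1000$ci_high,
            statistic = NA_real_,
            p_value = cx$table$p_value[cx$table$term == "ttils_count"],
            n = cx$table$n[1], n_events = cx$table$n_events[1]
          )
        )
      }
    }
  }

  # association battery over available groupings
  cohort2 <- dplyr::mutate(
    cohort,
    age_group = if ("age_years" %in% names(cohort)) {
      ifelse(.data$age_years < 50, "<50", ">=50")
    } else {
      NA_character_
    },
    size_group = if ("size_cm" %in% names(cohort)) {
      ifelse(.data$size_cm < 2, "<2cm", ">=2cm")
    } else {
      NA_character_
    }
  )
  groupings <- intersect(
    c("age_group", "size_group", "grade", "ln_positive", "ki67_high",
      "lvi", "npi_group", "pr_positive"),
    names(cohort2)
  )
  associations <- association_battery(cohort2, features, groupings)

  # correlation panel
  correlations <- tibble::tibble()
  panel <- list(c("stils_count", "ttils_count"),
                c("stils_count", "stils_pct"))
  for (pr in panel) {
    if (all(pr %in% names(cohort))) {
      correlations <- dplyr::bind_rows(
        correlations,
        dplyr::mutate(correlation(cohort[[pr[1]]], cohort[[pr[2]]]),
                      x = pr[1], y = pr[2], .before = 1)
      )
    }
  }

  icc_tab <- tibble::tibble()
  if (all(c("visual_stils_pct", "stils_pct") %in% names(cohort))) {
    ag <- icc_agreement(cohort$visual_stils_pct, cohort$stils_pct)
    icc_tab <- tibble::tibble(icc = ag$icc, model = ag$model,
                              n_subjects = ag$n_subjects,
                              n_raters = ag$n_raters)
  }

  write_cohort(cohort, file.path(out_dir, "cohort_with_features.csv"))
  readr::write_csv(cutpoints, file.path(out_dir, "cutpoints.csv"),
                   progress = FALSE)
  readr::write_csv(surv_results, file.path(out_dir, "survival_results.csv"),
                   progress = FALSE)
  readr::write_csv(associations, file.path(out_dir, "associations.csv"),
                   progress = FALSE)
  readr::write_csv(correlations, file.path(out_dir, "correlations.csv"),
                   progress = FALSE)
  readr::write_csv(icc_tab, file.path(out_dir, "icc.csv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tilscape")),
    seed = seed,
    test_fraction = test_fraction,
    min_group_fraction = min_group_fraction,
    features = features,
    n_patients = nrow(cohort),
    n_events = n_events,
    config_hash = rlang::hash(list(seed, test_fraction,
                                   min_group_fraction, features)),
    audit_discovery_rows = which(cohort$split_label == "discovery"),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, cutpoints = cutpoints,
                 survival_results = surv_results,
                 associations = associations,
                 correlations = correlations, icc = icc_tab,
                 manifest = manifest))
}

#' Compute and write per-slide features for a set of slides
#'
#' Features-only mode: each slide's nuclei table and masks are scored
#' with [compute_slide_features()] and written as one JSON document per
#' slide plus a joined summary table.
#'
#' @param slides named list; each element a list with `nuclei` (tibble)
#'   and `masks` ([region_mask_set()]), e.g. a `synthetic_slide`.
#' @param out_dir output directory.
#' @param config a [til_config()].
#' @return tibble of per-slide features (one row per slide).
#' @export
run_features_stage <- function(slides, out_dir, config = til_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  feat_dir <- file.path(out_dir, "features")
  if (!dir.exists(feat_dir)) dir.create(feat_dir)
  ids <- names(slides) %||% sprintf("slide_%03d", seq_along(slides))
  rows <- purrr::imap_dfr(stats::setNames(slides, ids), function(sl, id) {
    sf <- compute_slide_features(sl$nuclei, sl$masks, config)
    write_features(sf, file.path(feat_dir, paste0(id, ".json")))
    dplyr::mutate(tidy(sf), slide_id = id, .before = 1)
  })
  readr::write_csv(rows, file.path(out_dir, "slide_features.csv"),
                   progress = FALSE)
  rows
}
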