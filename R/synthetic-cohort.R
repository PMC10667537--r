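#' Configuration for synthetic cohort generation
#'
#' A shared per-patient latent immune intensity drives both the stromal
#' and intratumoural TILs counts (inducing their positive correlation),
#' the ordinal clinicopathological covariates (via thresholded linked
#' latents) and, through the standardized log TILs burden, an
#' exponential proportional-hazards survival time with administrative
#' censoring.
#'
#' Defaults describe a luminal breast-cancer cohort: sTILs counts an
#' order of magnitude above tTILs counts, a model sTILs-tTILs
#' correlation of ~0.65-0.7, ~15-20% breast-cancer deaths over a 240-month
#' horizon, a TILs log-hazard of `log(1.7)` per standard deviation of
#' log(1 + total TILs), and a visual scorer agreeing with the automated
#' sTILs percentage at ICC ~0.7.
#'
#' @param n_patients cohort size (>= 2).
#' @param mean_stils,mean_ttils expected sTILs / tTILs counts per slide.
#' @param latent_shared_sd SD of the shared log-normal latent component
#'   (drives the sTILs-tTILs correlation upward).
#' @param latent_noise_sd SD of the per-compartment idiosyncratic
#'   log-normal component (drives it downward).
#' @param beta_tils log hazard ratio per SD of log(1 + total TILs).
#' @param baseline_hazard exponential baseline hazard per month (> 0).
#' @param censor_horizon administrative censoring time in months.
#' @param covariate_link correlation of the covariate latents with the
#'   shared immune latent, in [0, 1).
#' @param visual_agreement_icc target intraclass correlation between the
#'   visual and automated sTILs percentage, in (0, 1].
#' @param seed integer seed (mandatory).
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 1000,
                              mean_stils = 800, mean_ttils = 150,
                              latent_shared_sd = 0.8, latent_noise_sd = 0.45,
                              beta_tils = log(1.7),
                              baseline_hazard = 8e-4, censor_horizon = 240,
                              covariate_link = 0.5,
                              visual_agreement_icc = 0.7, seed = 1) {
  stopifnot(
    n_patients >= 2, mean_stils > 0, mean_ttils > 0,
    latent_shared_sd >= 0, latent_noise_sd >= 0,
    baseline_hazard > 0, censor_horizon > 0,
    covariate_link >= 0, covariate_link < 1,
    visual_agreement_icc > 0, visual_agreement_icc <= 1
  )
  structure(list(
    n_patients = n_patients, mean_stils = mean_stils,
    mean_ttils = mean_ttils, latent_shared_sd = latent_shared_sd,
    latent_noise_sd = latent_noise_sd, beta_tils = beta_tils,
    baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
    covariate_link = covariate_link,
    visual_agreement_icc = visual_agreement_icc, seed = seed
  ), class = "cohort_sim_config")
}

#' Generate a synthetic cohort with planted TILs features and survival
#'
#' @param config a [cohort_sim_config()].
#' @return tibble with one row per patient: identifiers, covariates
#'   (`age_years`, `size_cm`, `grade`, `ln_positive`, `lvi`,
#'   `npi_group`, `pr_positive`, `ki67_high`), planted slide features
#'   (`stils_count`, `ttils_count`, `total_tils`, `stils_pct`,
#'   `stroma_immune_cooc`, `tumour_immune_cooc`), `visual_stils_pct`,
#'   `tils_z` (the standardized log TILs burden that drives the hazard),
#'   survival (`time_months`, `event`) and `split_label` (all
#'   `"unassigned"`).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    w <- config$latent_shared_sd
    s <- config$latent_noise_sd
    adj <- (w^2 + s^2) / 2  # keep E[lambda] at the requested means
    z_shared <- stats::rnorm(n)

    lam_s <- exp(log(config$mean_stils) + w * z_shared +
                   s * stats::rnorm(n) - adj)
    lam_t <- exp(log(config$mean_ttils) + w * z_shared +
                   s * stats::rnorm(n) - adj)
    stils <- stats::rpois(n, lam_s)
    ttils <- stats::rpois(n, lam_t)
    other_immune <- stats::rpois(n, 0.05 * lam_s)
    total <- stils + ttils + other_immune

    # co-occurrence scores scale with the counts they involve
    stroma_cooc <- stats::rpois(n, 3 * stils)
    tumour_cooc <- stats::rpois(n, 3 * ttils)

    # AI-based sTILs percentage from counts over a variable TAS area
    tas_area <- exp(stats::rnorm(n, log(3e5), 0.4))
    stils_pct <- pmin(100, 100 * 28 * stils / tas_area)
    # visual scorer: additive noise sized for the target ICC; the noise
    # sits on one rater only, so half its variance enters the
    # agreement-ICC denominator
    icc <- config$visual_agreement_icc
    noise_sd <- stats::sd(stils_pct) * sqrt(2 * (1 - icc) / icc)
    visual <- pmax(0, stils_pct + stats::rnorm(n, 0, noise_sd))

    # covariates linked to the shared immune latent
    rho <- config$covariate_link
    link <- function() rho * z_shared + sqrt(1 - rho^2) * stats::rnorm(n)
    grade <- cut(link(), c(-Inf, stats::qnorm(0.25), stats::qnorm(0.60), Inf),
                 labels = FALSE)
    size_cm <- round(exp(0.6 + 0.25 * link()), 1)
    ln_positive <- link() > stats::qnorm(0.65)
    ki67_high <- link() > stats::qnorm(0.55)
    lvi <- link() > stats::qnorm(0.75)
    pr_positive <- stats::runif(n) < 0.7  # unlinked
    age_years <- round(58 - 4 * z_shared + stats::rnorm(n, 0, 9))
    npi <- 0.2 * size_cm + grade + ifelse(ln_positive, 2, 1)
    npi_group <- cut(npi, c(-Inf, 3.4, 5.4, Inf),
                     labels = c("good", "moderate", "poor"))

    # exponential PH survival on the standardized log TILs burden
    tils_z <- as.numeric(scale(log1p(total)))
    hazard <- config$baseline_hazard * exp(config$beta_tils * tils_z)
    t_event <- stats::rexp(n, hazard)
    event <- t_event <= config$censor_horizon
    time_months <- pmin(t_event, config$censor_horizon)

    tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_years = age_years, size_cm = size_cm, grade = grade,
      ln_positive = ln_positive, lvi = lvi,
      npi_group = as.character(npi_group), pr_positive = pr_positive,
      ki67_high = ki67_high,
      stils_count = stils, ttils_count = ttils, total_tils = total,
      stils_pct = stils_pct,
      stroma_immune_cooc = stroma_cooc, tumour_immune_cooc = tumour_cooc,
      visual_stils_pct = visual, tils_z = tils_z,
      time_months = time_months, event = event,
      split_label = "unassigned"
    )
  })
}

#' Read / write a cohort table
#'
#' The cohort CSV has one row per patient; required columns are
#' `patient_id`, `time_months` (> 0) and `event` (logical or 0/1); all
#' other columns (covariates, joined slide features) pass through.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("patient_id", "time_months", "event"), names(df))
  if (length(missing)) {
    stop("Cohort table is missing required column(s): ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("`patient_id` must be unique.", call. = FALSE)
  }
  validate_surv(df$time_months, df$event)
  df$event <- as.logical(df$event)
  df
}

#' @rdname read_cohort
#' @param cohort tibble with one row per patient.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
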