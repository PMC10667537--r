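#' Configuration for synthetic slide generation
#'
#' Describes a virtual slide at the nuclei-map scale: tumour nests as
#' random discs in a tissue field, homogeneous Poisson tumour/stromal
#' nuclei inside their regions, and immune nuclei split between stroma
#' and tumour, with the stromal immune component optionally concentrated
#' near tumour borders (sTILs hugging the invasive margin). Densities
#' are nuclei per 1000 px^2.
#'
#' @param width,height slide size in pixels.
#' @param n_tumour_nests number of tumour discs.
#' @param nest_radius_range length-2 positive range of disc radii (px).
#' @param tumour_density,stroma_density nuclei per 1000 px^2 of their
#'   region.
#' @param immune_intensity slide-level immune rate (immune nuclei per
#'   1000 px^2 of tissue), `>= 0`.
#' @param stromal_fraction_of_immune fraction of immune nuclei placed in
#'   stroma rather than tumour (default 0.8: stromal TILs outnumber
#'   intratumoural TILs).
#' @param border_attraction `>= 0`; stromal immune placement weight is
#'   `exp(-border_attraction * d / 16)` with `d` the pixel's distance to
#'   the tumour region (0 = uniform).
#' @param seed integer seed (mandatory).
#' @return list of class `slide_sim_config`.
#' @export
slide_sim_config <- function(width = 256, height = 256, n_tumour_nests = 4,
                             nest_radius_range = c(18, 40),
                             tumour_density = 6, stroma_density = 4,
                             immune_intensity = 2,
                             stromal_fraction_of_immune = 0.8,
                             border_attraction = 1, seed = 1) {
  stopifnot(
    width >= 8, height >= 8, n_tumour_nests >= 0,
    length(nest_radius_range) == 2, all(nest_radius_range > 0),
    tumour_density >= 0, stroma_density >= 0, immune_intensity >= 0,
    stromal_fraction_of_immune >= 0, stromal_fraction_of_immune <= 1,
    border_attraction >= 0
  )
  structure(list(
    width = width, height = height, n_tumour_nests = n_tumour_nests,
    nest_radius_range = nest_radius_range,
    tumour_density = tumour_density, stroma_density = stroma_density,
    immune_intensity = immune_intensity,
    stromal_fraction_of_immune = stromal_fraction_of_immune,
    border_attraction = border_attraction, seed = seed
  ), class = "slide_sim_config")
}

# sample k nucleus centroids on the TRUE pixels of `mask`, optionally
# weighted; jitter keeps the rounded centroid inside the source pixel
sample_in_mask <- function(mask, k, weights = NULL) {
  px <- which(mask)
  if (!length(px) || k == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  pick <- if (is.null(weights)) {
    px[sample.int(length(px), k, replace = TRUE)]
  } else {
    px[sample.int(length(px), k, replace = TRUE, prob = weights)]
  }
  H <- nrow(mask)
  row <- ((pick - 1L) %% H) + 1L
  col <- ((pick - 1L) %/% H) + 1L
  tibble::tibble(
    x = (col - 1L) + stats::runif(k, -0.49, 0.49),
    y = (row - 1L) + stats::runif(k, -0.49, 0.49)
  )
}

#' Generate a synthetic slide with known ground truth
#'
#' Builds masks and nuclei per `config`, then labels every planted
#' nucleus against the same analysis regions the scoring pipeline uses
#' (DCIS/artefact masks are empty by construction), recording exact
#' ground-truth counts.
#'
#' @param config a [slide_sim_config()].
#' @param til_cfg a [til_config()] used for the ground-truth region
#'   geometry (TAS radii).
#' @return list of class `synthetic_slide`: `nuclei` (tibble),
#'   `masks` ([region_mask_set()]), `regions` ([analysis_regions()]),
#'   `ground_truth` (list: `stils_count`, `ttils_count`, `total_tils`,
#'   `n_by_type`).
#' @export
generate_slide <- function(config = slide_sim_config(),
                           til_cfg = til_config()) {
  stopifnot(inherits(config, "slide_sim_config"))
  with_seed(config$seed, {
    W <- config$width
    H <- config$height
    margin <- 2L
    tissue <- matrix(FALSE, H, W)
    tissue[(margin + 1):(H - margin), (margin + 1):(W - margin)] <- TRUE

    tumour <- matrix(FALSE, H, W)
    if (config$n_tumour_nests > 0) {
      cx <- stats::runif(config$n_tumour_nests, 0.15 * W, 0.85 * W)
      cy <- stats::runif(config$n_tumour_nests, 0.15 * H, 0.85 * H)
      rr <- stats::runif(config$n_tumour_nests,
                         config$nest_radius_range[1],
                         config$nest_radius_range[2])
      xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
      ys <- matrix(rep(seq_len(H) - 1, times = W), H, W)
      for (i in seq_len(config$n_tumour_nests)) {
        tumour <- tumour | ((xs - cx[i])^2 + (ys - cy[i])^2 <= rr[i]^2)
      }
      tumour <- tumour & tissue
    }
    stroma <- tissue & !tumour

    if (config$tumour_density > 0 && !any(tumour)) {
      warning("Tumour region is empty; no tumour nuclei placed.",
              call. = FALSE)
    }

    n_tum <- stats::rpois(1, config$tumour_density * sum(tumour) / 1000)
    n_str <- stats::rpois(1, config$stroma_density * sum(stroma) / 1000)
    n_imm <- stats::rpois(1, config$immune_intensity * sum(tissue) / 1000)
    n_imm_tum <- stats::rbinom(1, n_imm,
                               1 - config$stromal_fraction_of_immune)
    if (!any(tumour)) n_imm_tum <- 0L
    n_imm_str <- n_imm - n_imm_tum
    if (!any(stroma)) n_imm_str <- 0L

    w_str <- NULL
    if (config$border_attraction > 0 && any(tumour) && any(stroma)) {
      d <- sqrt(sq_dist_to(tumour))
      w_str <- exp(-config$border_attraction * d[which(stroma)] / 16)
    }

    pts <- dplyr::bind_rows(
      dplyr::mutate(sample_in_mask(tumour, n_tum), type = "tumour"),
      dplyr::mutate(sample_in_mask(stroma, n_str), type = "stromal"),
      dplyr::mutate(sample_in_mask(tumour, n_imm_tum), type = "immune"),
      dplyr::mutate(sample_in_mask(stroma, n_imm_str, weights = w_str),
                    type = "immune")
    )
    nuclei <- nuclei_table(pts$x, pts$y, pts$type)

    masks <- suppressMessages(region_mask_set(
      list(tissue = tissue, tumour = tumour, stroma = stroma),
      scale_note = "synthetic nuclei-map grid"
    ))
    regions <- capture_tas(
      tumour, stroma,
      dilation_radius = til_cfg$tas_dilation_radius,
      fill_radius = til_cfg$tas_fill_radius,
      fill_mode = til_cfg$tas_fill_mode,
      tissue = tissue
    )
    labelled <- assign_regions(nuclei, regions)
    imm <- labelled$nucleus_type == "immune"
    ground_truth <- list(
      stils_count = sum(imm & labelled$region_label == "tas"),
      ttils_count = sum(imm & labelled$region_label == "tumour_region"),
      total_tils = sum(imm & labelled$region_label != "excluded"),
      n_by_type = table(labelled$nucleus_type)
    )
    structure(list(nuclei = nuclei, masks = masks, regions = regions,
                   ground_truth = ground_truth, config = config),
              class = "synthetic_slide")
  })
}

#' Write a synthetic slide as standard pipeline inputs
#'
#' Nuclei go to `nuclei.csv` and masks to PNG rasters, so synthetic and
#' real slides enter the pipeline identically.
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nuclei(slide$nuclei, file.path(dir, "nuclei.csv"))
  write_masks(slide$masks, dir)
  invisible(dir)
}
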