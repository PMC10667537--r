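#' Configuration for per-slide TILs feature computation
#'
#' @param tas_dilation_radius disc radius (px) for the tumour dilation of
#'   the TAS capture (default 8).
#' @param tas_fill_radius disc radius (px) for the hole-filling step
#'   (default 32).
#' @param tas_fill_mode `"close_then_fill"` or `"fill_only"`; see
#'   [capture_tas()].
#' @param cooc_radius_px co-occurrence distance in pixels (default 32):
#'   two nuclei co-occur when their centroids lie within this Euclidean
#'   distance.
#' @param default_nucleus_area pixel area assumed for a nucleus whose
#'   polygon area is unknown, used only by the sTILs percentage
#'   (default 28 px).
#' @return a list of class `til_config`.
#' @export
til_config <- function(tas_dilation_radius = 8, tas_fill_radius = 32,
                       tas_fill_mode = "close_then_fill",
                       cooc_radius_px = 32, default_nucleus_area = 28) {
  assert_scalar_number(cooc_radius_px, "cooc_radius_px", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(default_nucleus_area, "default_nucleus_area", min = 0)
  structure(list(
    tas_dilation_radius = tas_dilation_radius,
    tas_fill_radius = tas_fill_radius,
    tas_fill_mode = tas_fill_mode,
    cooc_radius_px = cooc_radius_px,
    default_nucleus_area = default_nucleus_area
  ), class = "til_config")
}

REGION_LABELS <- c("tumour_region", "tas", "other", "excluded")

#' Assign each nucleus to an analysis region
#'
#' A nucleus at `(x, y)` belongs to the region whose mask is set at the
#' pixel containing its rounded centroid (round-half-up); nuclei on no
#' region or outside the grid are labelled `excluded` and take no part in
#' downstream features.
#'
#' @param nuclei tibble from [nuclei_table()].
#' @param regions an [analysis_regions()] object.
#' @return `nuclei` with an added `region_label` factor column.
#' @export
assign_regions <- function(nuclei, regions) {
  stopifnot(inherits(regions, "analysis_regions"))
  H <- nrow(regions$tumour_eff)
  W <- ncol(regions$tumour_eff)
  row <- round_half_up(nuclei$y) + 1  # 0-based y -> 1-based matrix row
  col <- round_half_up(nuclei$x) + 1
  oob <- row < 1 | row > H | col < 1 | col > W
  if (any(oob)) {
    warning(sum(oob), " nucleus/nuclei outside the mask grid; ",
            "labelled 'excluded'.", call. = FALSE)
  }
  idx <- cbind(pmin(pmax(row, 1), H), pmin(pmax(col, 1), W))
  label <- rep("excluded", nrow(nuclei))
  inb <- !oob
  label[inb & regions$tumour_eff[idx]] <- "tumour_region"
  label[inb & regions$tas[idx]] <- "tas"
  label[inb & regions$other[idx]] <- "other"
  dplyr::mutate(nuclei,
                region_label = factor(label, levels = REGION_LABELS))
}

#' Count stromal and intratumoural TILs
#'
#' The sTILs count is the number of immune nuclei scattered in
#' tumour-associated stroma; the tTILs count is the number of immune
#' nuclei inside the tumour region itself; total TILs counts immune
#' nuclei anywhere outside excluded areas.
#'
#' @param labelled tibble from [assign_regions()].
#' @return one-row tibble with `stils_count`, `ttils_count`,
#'   `total_tils`.
#' @export
count_tils <- function(labelled) {
  imm <- labelled$nucleus_type == "immune"
  lab <- labelled$region_label
  tibble::tibble(
    stils_count = sum(imm & lab == "tas"),
    ttils_count = sum(imm & lab == "tumour_region"),
    total_tils = sum(imm & lab != "excluded")
  )
}

#' AI-based sTILs percentage
#'
#' The percentage of the tumour-associated stroma area occupied by
#' immune nuclei, mimicking the pathologist's visual stromal-TILs score:
#' `100 * sum(area of immune nuclei in TAS) / (TAS pixel area)`, clamped
#' to `[0, 100]`. Nuclei without a measured polygon area contribute
#' `default_nucleus_area` pixels each.
#'
#' @inheritParams assign_regions
#' @param default_nucleus_area fallback per-nucleus area in pixels
#'   (default 28).
#' @return a single percentage, or `NA` (undefined, with a warning) when
#'   the TAS is empty.
#' @export
stils_percentage <- function(labelled, regions, default_nucleus_area = 28) {
  stopifnot(inherits(regions, "analysis_regions"))
  tas_area <- sum(regions$tas)
  if (tas_area == 0) {
    warning("TAS area is 0: sTILs percentage undefined, returning NA.",
            call. = FALSE)
    return(NA_real_)
  }
  sel <- labelled$nucleus_type == "immune" & labelled$region_label == "tas"
  areas <- labelled$area_px[sel]
  areas[is.na(areas)] <- default_nucleus_area
  pct <- 100 * sum(areas) / tas_area
  if (pct > 100) {
    warning("Immune nucleus area exceeds TAS area; clamping percentage ",
            "to 100.", call. = FALSE)
    pct <- 100
  }
  pct
}

#' Cell-type co-occurrence matrix
#'
#' Counts, for each ordered pair of nucleus types among tumour, stromal
#' and immune, the unordered nucleus pairs whose centroids lie within
#' `radius_px` of each other. Each cross-type pair increments both
#' `cm[a, b]` and `cm[b, a]`; same-type pairs are counted once on the
#' diagonal, so the matrix is symmetric by construction. Excluded nuclei
#' and types out of scope never participate.
#'
#' Pairs are found with a uniform-grid spatial index (cell side =
#' radius, 3 x 3 neighbourhood scan); the result is identical to the
#' quadratic all-pairs computation.
#'
#' @param labelled tibble from [assign_regions()] (an unlabelled nuclei
#'   table is accepted and used whole).
#' @param radius_px co-occurrence distance, `> 0`.
#' @param types ordered character vector of types in scope.
#' @return symmetric integer matrix with `types` dimnames.
#' @export
cooccurrence_matrix <- function(labelled, radius_px = 32, types = CM_TYPES) {
  assert_scalar_number(radius_px, "radius_px", min = 0, strict_min = TRUE)
  keep <- labelled$nucleus_type %in% types
  if ("region_label" %in% names(labelled)) {
    keep <- keep & labelled$region_label != "excluded"
  }
  x <- labelled$x[keep]
  y <- labelled$y[keep]
  type_i <- match(as.character(labelled$nucleus_type[keep]), types)
  K <- length(types)
  cm <- matrix(0L, K, K, dimnames = list(types, types))
  n <- length(x)
  if (n >= 2L) {
    cx <- floor(x / radius_px)
    cy <- floor(y / radius_px)
    cell <- paste(cx, cy)
    by_cell <- split(seq_len(n), cell)
    cell_xy <- do.call(rbind, lapply(strsplit(names(by_cell), " "), as.numeric))
    key <- function(a, b) paste(a, b)
    cell_pos <- stats::setNames(seq_along(by_cell), names(by_cell))
    r2 <- radius_px^2
    for (ci in seq_along(by_cell)) {
      a_idx <- by_cell[[ci]]
      # same cell: all pairs within the cell
      cm <- tally_pairs(cm, x, y, type_i, a_idx, a_idx, r2, same = TRUE)
      # forward half of the 3x3 neighbourhood (avoid double visits)
      for (off in list(c(1, -1), c(1, 0), c(1, 1), c(0, 1))) {
        nb <- cell_pos[key(cell_xy[ci, 1] + off[1], cell_xy[ci, 2] + off[2])]
        if (!is.na(nb)) {
          cm <- tally_pairs(cm, x, y, type_i, a_idx, by_cell[[nb]], r2,
                            same = FALSE)
        }
      }
    }
  }
  cm
}

# accumulate co-occurring pairs between index sets a and b into cm
tally_pairs <- function(cm, x, y, type_i, a, b, r2, same) {
  if (same) {
    if (length(a) < 2L) return(cm)
    pr <- utils::combn(a, 2L)
    i <- pr[1, ]
    j <- pr[2, ]
  } else {
    g <- expand.grid(i = a, j = b)
    i <- g$i
    j <- g$j
  }
  d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
  hit <- d2 <= r2
  if (!any(hit)) return(cm)
  ti <- type_i[i[hit]]
  tj <- type_i[j[hit]]
  K <- nrow(cm)
  # cross-type pairs increment both (a,b) and (b,a); same-type once
  inc <- tabulate(c((tj - 1L) * K + ti, ((ti - 1L) * K + tj)[ti != tj]),
                  nbins = K * K)
  cm + matrix(inc, K, K, dimnames = dimnames(cm))
}

#' Scalar features of a co-occurrence matrix
#'
#' `stroma_immune_cooc` and `tumour_immune_cooc` are the corresponding
#' CM cells. The CM is then normalised over its upper triangle
#' (including the diagonal) into a distribution `P` over unordered type
#' pairs; `heterogeneity` is the Shannon entropy of `P` in bits and
#' `contrast` is the immune-involving off-diagonal mass
#' (`P[tumour, immune] + P[stromal, immune]`). An all-zero CM yields all
#' features 0.
#'
#' @param cm symmetric nonnegative matrix with `tumour`, `stromal`,
#'   `immune` dimnames.
#' @return one-row tibble with the four scalars.
#' @export
cm_features <- function(cm) {
  cm <- validate_cm(cm)
  s_i <- cm["stromal", "immune"]
  t_i <- cm["tumour", "immune"]
  upper <- cm[upper.tri(cm, diag = TRUE)]
  tot <- sum(upper)
  if (tot == 0) {
    het <- 0
    contrast <- 0
  } else {
    p <- upper / tot
    p <- p[p > 0]
    het <- -sum(p * log2(p))
    contrast <- (t_i + s_i) / tot
  }
  tibble::tibble(
    stroma_immune_cooc = as.integer(s_i),
    tumour_immune_cooc = as.integer(t_i),
    heterogeneity = het,
    contrast = contrast
  )
}

#' Compute all per-slide TILs features
#'
#' Composes the full per-slide pipeline: exclusion of DCIS/artefact
#' pixels, TAS capture, nucleus-region assignment, sTILs/tTILs counting,
#' AI-based sTILs percentage, co-occurrence matrix and its scalars.
#' Deterministic for fixed inputs and configuration, and invariant to
#' the input order of nuclei.
#'
#' @param nuclei tibble from [nuclei_table()] / [read_nuclei()].
#' @param masks a [region_mask_set()].
#' @param config a [til_config()].
#' @return a [slide_features()] object.
#' @export
compute_slide_features <- function(nuclei, masks, config = til_config()) {
  stopifnot(inherits(masks, "region_mask_set"), inherits(config, "til_config"))
  cleaned <- apply_exclusions(masks)
  regions <- capture_tas(
    cleaned$tumour, cleaned$stroma,
    dilation_radius = config$tas_dilation_radius,
    fill_radius = config$tas_fill_radius,
    fill_mode = config$tas_fill_mode,
    tissue = cleaned$tissue
  )
  labelled <- assign_regions(nuclei, regions)
  counts <- count_tils(labelled)
  pct <- if (sum(regions$tas) == 0) NA_real_ else {
    stils_percentage(labelled, regions, config$default_nucleus_area)
  }
  cm <- cooccurrence_matrix(labelled, radius_px = config$cooc_radius_px)
  cmf <- cm_features(cm)
  slide_features(
    stils_count = counts$stils_count,
    ttils_count = counts$ttils_count,
    total_tils = counts$total_tils,
    stils_pct = pct,
    cm = cm,
    heterogeneity = cmf$heterogeneity,
    contrast = cmf$contrast
  )
}
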