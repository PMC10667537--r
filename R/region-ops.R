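#' Generate a tissue mask from an RGB or grayscale image
#'
#' Standard histology foreground detection: convert to grayscale, invert
#' (tissue is darker than the glass background), threshold globally
#' (Otsu's method by default), drop small objects and fill holes.
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array, values in
#'   `[0, 1]`.
#' @param threshold optional fixed threshold on the inverted intensity;
#'   when `NULL` (default) Otsu's method picks it from a 256-bin
#'   histogram.
#' @param min_object_area objects smaller than this many pixels are
#'   removed (default 64).
#' @return logical matrix, `TRUE` where tissue.
#' @export
compute_tissue_mask <- function(img, threshold = NULL, min_object_area = 64) {
  if (length(dim(img)) == 3L) {
    img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix or an H x W x 3 array.",
         call. = FALSE)
  }
  inv <- 1 - img
  if (diff(range(img)) < .Machine$double.eps) {
    warning("Constant-intensity image: threshold undefined, returning ",
            "an empty tissue mask.", call. = FALSE)
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  thr <- threshold %||% otsu_threshold(inv)
  mask <- inv > thr
  mask <- remove_small_objects(mask, min_object_area)
  fill_holes(mask)
}

# Otsu's method on a 256-bin histogram of values in [0, 1]:
# maximise between-class variance of the split.
otsu_threshold <- function(v) {
  breaks <- seq(0, 1, length.out = 257)
  h <- tabulate(findInterval(pmin(pmax(v, 0), 1), breaks,
                             rightmost.closed = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-257] + breaks[-1]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Remove DCIS and artefact pixels from the analysis masks
#'
#' In-situ carcinoma and annotated artefacts (necrosis, calcification,
#' image defects) take no part in TILs scoring: their pixels are removed
#' from the tumour, stroma and tissue masks, and nuclei falling on them
#' are later dropped.
#'
#' @param masks a [region_mask_set()].
#' @return a new `region_mask_set` with exclusions applied (its `dcis`
#'   and `excluded` masks record what was removed).
#' @export
apply_exclusions <- function(masks) {
  stopifnot(inherits(masks, "region_mask_set"))
  drop <- masks$dcis | masks$excluded
  if (!any(drop)) {
    return(masks)
  }
  out <- list(
    tissue = masks$tissue & !drop,
    tumour = masks$tumour & !drop,
    stroma = masks$stroma & !drop,
    dcis = masks$dcis,
    excluded = masks$excluded
  )
  if (!any(out$tissue) && any(masks$tissue)) {
    warning("Exclusions removed all tissue pixels.", call. = FALSE)
  }
  # bypass the constructor's repair messages: exclusions cannot create
  # tumour/stroma overlap or tissue escapees
  structure(out,
            width = attr(masks, "width"), height = attr(masks, "height"),
            scale_note = attr(masks, "scale_note"),
            class = "region_mask_set")
}

#' Disjoint analysis regions for TILs scoring
#'
#' @param tumour_eff,tas,other pairwise-disjoint logical matrices of one
#'   shape: effective (invasive, non-excluded) tumour, tumour-associated
#'   stroma, and remaining tissue.
#' @return object of class `analysis_regions`.
#' @export
analysis_regions <- function(tumour_eff, tas, other) {
  tumour_eff <- as_binary_matrix(tumour_eff, "tumour_eff")
  tas <- as_binary_matrix(tas, "tas")
  other <- as_binary_matrix(other, "other")
  stopifnot(identical(dim(tumour_eff), dim(tas)),
            identical(dim(tumour_eff), dim(other)))
  if (any(tumour_eff & tas) || any(tumour_eff & other) || any(tas & other)) {
    stop("Analysis regions must be pairwise disjoint.", call. = FALSE)
  }
  structure(list(tumour_eff = tumour_eff, tas = tas, other = other),
            class = "analysis_regions")
}

#' @export
print.analysis_regions <- function(x, ...) {
  cat("<analysis_regions>",
      sprintf("tumour %d px, TAS %d px, other %d px\n",
              sum(x$tumour_eff), sum(x$tas), sum(x$other)))
  invisible(x)
}

#' Capture tumour-associated stroma (TAS)
#'
#' Morphological recipe: the tumour mask is dilated with a Euclidean
#' disc of radius `dilation_radius`, holes are filled with a disc of
#' radius `fill_radius`, and any stroma captured inside the resulting
#' tumour envelope is TAS. With the default `fill_mode =
#' "close_then_fill"` the hole-filling step is a morphological closing
#' with `disc(fill_radius)` followed by binary hole filling, so both
#' narrow stromal channels (width below ~`2 * fill_radius`) and fully
#' enclosed stroma are captured; `fill_mode = "fill_only"` instead fills
#' only fully enclosed holes whose inscribed-disc radius is at most
#' `fill_radius`.
#'
#' Masks are padded with background by `dilation_radius + fill_radius`
#' before the morphology and cropped afterwards, so image edges never
#' create artificial TAS. Discs are closed Euclidean balls on pixel
#' centres.
#'
#' @param tumour,stroma disjoint logical matrices of one shape.
#' @param dilation_radius disc radius (pixels) for the tumour dilation
#'   (default 8).
#' @param fill_radius disc radius (pixels) for hole filling (default 32).
#' @param fill_mode `"close_then_fill"` (default) or `"fill_only"`.
#' @param tissue optional tissue mask used to compute the `other`
#'   region; defaults to `tumour | stroma`.
#' @return an [analysis_regions()] object: `tumour_eff` (the input
#'   tumour), `tas` (envelope-captured stroma), `other` (remaining
#'   tissue).
#' @export
capture_tas <- function(tumour, stroma, dilation_radius = 8, fill_radius = 32,
                        fill_mode = c("close_then_fill", "fill_only"),
                        tissue = NULL) {
  fill_mode <- match.arg(fill_mode)
  tumour <- as_binary_matrix(tumour, "tumour")
  stroma <- as_binary_matrix(stroma, "stroma")
  assert_scalar_number(dilation_radius, "dilation_radius", min = 0)
  assert_scalar_number(fill_radius, "fill_radius", min = 0)
  if (!identical(dim(tumour), dim(stroma))) {
    stop("`tumour` and `stroma` must share one shape.", call. = FALSE)
  }
  if (any(tumour & stroma)) {
    stop("`tumour` and `stroma` must be disjoint (see region_mask_set()).",
         call. = FALSE)
  }
  tissue <- if (is.null(tissue)) tumour | stroma else as_binary_matrix(tissue)

  envelope <- tumour_envelope(tumour, dilation_radius, fill_radius, fill_mode)
  tas <- envelope & stroma
  other <- tissue & !tumour & !tas
  analysis_regions(tumour_eff = tumour, tas = tas, other = other)
}

tumour_envelope <- function(tumour, dilation_radius, fill_radius, fill_mode) {
  if (!any(tumour)) {
    return(tumour)
  }
  pad <- ceiling(dilation_radius + fill_radius) + 1L
  H <- nrow(tumour)
  W <- ncol(tumour)
  big <- matrix(FALSE, H + 2L * pad, W + 2L * pad)
  big[pad + seq_len(H), pad + seq_len(W)] <- tumour
  big <- mask_dilate(big, dilation_radius)
  if (fill_mode == "close_then_fill") {
    big <- fill_holes(mask_close(big, fill_radius))
  } else {
    big <- fill_small_holes(big, fill_radius)
  }
  big[pad + seq_len(H), pad + seq_len(W)]
}

# fill only holes whose largest inscribed disc has radius <= r
fill_small_holes <- function(mask, r) {
  bg <- label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole_ids <- setdiff(unique(bg[bg > 0L]), border)
  if (!length(hole_ids)) {
    return(mask)
  }
  dist_sq <- sq_dist_to(mask)  # distance to foreground
  out <- mask
  for (h in hole_ids) {
    px <- bg == h
    inscribed_sq <- max(dist_sq[px])
    if (inscribed_sq <= r^2) out[px] <- TRUE
  }
  out
}
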