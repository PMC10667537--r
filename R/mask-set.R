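REGION_NAMES <- c("tissue", "tumour", "stroma", "dcis", "excluded")

#' Construct a co-registered set of region masks
#'
#' Bundles the binary rasters a slide analysis needs: tissue, invasive
#' tumour, stroma, in-situ carcinoma (DCIS) and excluded artefacts. All
#' masks must share one shape; two containment rules are enforced on
#' construction, mirroring how segmentation outputs are cleaned before
#' feature computation:
#'
#' * `tumour` and `stroma` are forced inside `tissue` (tissue is grown to
#'   cover them, with a message);
#' * overlap between `tumour` and `stroma` is removed from `stroma`, with
#'   a warning stating the pixel count.
#'
#' @param masks named list of logical/numeric matrices; recognised names
#'   are `tissue`, `tumour`, `stroma`, `dcis`, `excluded`. Missing masks
#'   default to all-background; a missing `tissue` defaults to
#'   `tumour | stroma`.
#' @param scale_note free-text provenance of the raster grid (e.g.
#'   `"5x-downsampled 40x WSI"`). No unit conversion is ever attempted;
#'   all radii and areas are in pixels of this grid.
#' @return an object of class `region_mask_set`: a named list of logical
#'   matrices plus `width`, `height` and `scale_note` attributes.
#' @export
region_mask_set <- function(masks, scale_note = "") {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    stop("`masks` must be a named list of matrices.", call. = FALSE)
  }
  unknown <- setdiff(names(masks), REGION_NAMES)
  if (length(unknown)) {
    stop("Unknown mask name(s): ", paste(unknown, collapse = ", "),
         ". Recognised: ", paste(REGION_NAMES, collapse = ", "), ".",
         call. = FALSE)
  }
  masks <- lapply(masks, as_binary_matrix)
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L) {
    stop("Masks do not share one shape: ",
         paste(sprintf("%s (%s)", names(dims), dims), collapse = ", "), ".",
         call. = FALSE)
  }
  H <- nrow(masks[[1]])
  W <- ncol(masks[[1]])
  empty <- matrix(FALSE, H, W)
  out <- stats::setNames(vector("list", length(REGION_NAMES)), REGION_NAMES)
  for (nm in REGION_NAMES) out[[nm]] <- masks[[nm]] %||% empty
  if (is.null(masks$tissue)) {
    out$tissue <- out$tumour | out$stroma
  }

  grown <- sum((out$tumour | out$stroma) & !out$tissue)
  if (grown > 0) {
    message("Growing tissue mask to cover ", grown,
            " tumour/stroma pixel(s) outside it.")
    out$tissue <- out$tissue | out$tumour | out$stroma
  }
  overlap <- sum(out$tumour & out$stroma)
  if (overlap > 0) {
    warning("tumour and stroma overlap on ", overlap,
            " pixel(s); removing them from stroma.", call. = FALSE)
    out$stroma <- out$stroma & !out$tumour
  }

  structure(out,
            width = W, height = H, scale_note = scale_note,
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat("<region_mask_set> ", attr(x, "width"), "x", attr(x, "height"),
      " px", sep = "")
  if (nzchar(attr(x, "scale_note"))) cat("  [", attr(x, "scale_note"), "]", sep = "")
  cat("\n")
  for (nm in REGION_NAMES) {
    cat(sprintf("  %-9s %d px\n", nm, sum(x[[nm]])))
  }
  invisible(x)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff") && !requireNamespace("tiff", quietly = TRUE)) {
    stop("Reading TIFF masks requires the 'tiff' package.", call. = FALSE)
  }
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("Unsupported raster format '.", ext, "' for ", path,
         " (PNG or TIFF expected).", call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    img <- img[, , 1L]
  }
  img
}

#' Read region masks from single-channel raster files
#'
#' Nonzero pixels are in-region. Masks are validated and repaired by
#' [region_mask_set()].
#'
#' @param paths_by_name named character vector of file paths; names must
#'   be among `tissue`, `tumour`, `stroma`, `dcis`, `excluded`.
#' @inheritParams region_mask_set
#' @return a [region_mask_set()].
#' @export
read_masks <- function(paths_by_name, scale_note = "") {
  if (is.null(names(paths_by_name)) || any(names(paths_by_name) == "")) {
    stop("`paths_by_name` must be a named character vector.", call. = FALSE)
  }
  masks <- lapply(paths_by_name, read_raster)
  region_mask_set(masks, scale_note = scale_note)
}

#' Write region masks as PNG rasters
#'
#' @param masks a [region_mask_set()].
#' @param dir output directory; one `<name>.png` per non-empty region
#'   (tissue is always written).
#' @return invisibly, the named vector of written paths.
#' @export
write_masks <- function(masks, dir) {
  stopifnot(inherits(masks, "region_mask_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in REGION_NAMES) {
    if (nm != "tissue" && !any(masks[[nm]])) next
    p <- file.path(dir, paste0(nm, ".png"))
    png::writePNG(matrix(as.numeric(masks[[nm]]), nrow(masks[[nm]])), p)
    paths[nm] <- p
  }
  invisible(paths)
}
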