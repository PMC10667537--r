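CM_TYPES <- c("tumour", "stromal", "immune")

#' Per-slide TILs feature bundle
#'
#' Collects the per-slide outputs of the scoring pipeline: stromal and
#' intratumoural TILs counts, the AI-based sTILs percentage, the
#' cell-type co-occurrence matrix (CM) over tumour/stromal/immune nuclei
#' and its derived scalars.
#'
#' @param stils_count immune nuclei in tumour-associated stroma.
#' @param ttils_count immune nuclei in the effective tumour region.
#' @param total_tils immune nuclei in any non-excluded region.
#' @param stils_pct percentage of TAS area occupied by immune nuclei,
#'   in `[0, 100]`; `NA` when the TAS is empty (undefined, not zero).
#' @param cm symmetric nonnegative integer matrix with dimnames
#'   `tumour`, `stromal`, `immune`.
#' @param heterogeneity Shannon entropy (bits) of the normalised CM.
#' @param contrast immune-involving off-diagonal CM mass fraction.
#' @return an object of class `slide_features`.
#' @export
slide_features <- function(stils_count, ttils_count, total_tils, stils_pct,
                           cm, heterogeneity, contrast) {
  cm <- validate_cm(cm)
  stopifnot(
    stils_count >= 0, ttils_count >= 0, total_tils >= 0,
    stils_count + ttils_count <= total_tils,
    is.na(stils_pct) || (stils_pct >= 0 && stils_pct <= 100),
    heterogeneity >= 0, contrast >= 0
  )
  structure(
    list(
      stils_count = as.integer(stils_count),
      ttils_count = as.integer(ttils_count),
      total_tils = as.integer(total_tils),
      stils_pct = as.numeric(stils_pct),
      cm = cm,
      stroma_immune_cooc = as.integer(cm["stromal", "immune"]),
      tumour_immune_cooc = as.integer(cm["tumour", "immune"]),
      heterogeneity = as.numeric(heterogeneity),
      contrast = as.numeric(contrast)
    ),
    class = "slide_features"
  )
}

validate_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("`cm` must be a square matrix.", call. = FALSE)
  }
  if (is.null(dimnames(cm))) {
    dimnames(cm) <- list(CM_TYPES[seq_len(nrow(cm))], CM_TYPES[seq_len(nrow(cm))])
  }
  if (any(cm < 0)) stop("`cm` entries must be nonnegative.", call. = FALSE)
  if (!isTRUE(all.equal(cm, t(cm)))) {
    stop("`cm` must be symmetric.", call. = FALSE)
  }
  storage.mode(cm) <- "integer"
  cm
}

#' @export
print.slide_features <- function(x, ...) {
  cat("<slide_features>\n")
  cat(sprintf("  sTILs %d | tTILs %d | total %d | sTILs%% %s\n",
              x$stils_count, x$ttils_count, x$total_tils,
              ifelse(is.na(x$stils_pct), "NA (empty TAS)",
                     sprintf("%.2f", x$stils_pct))))
  cat(sprintf("  co-occurrence: stroma-immune %d, tumour-immune %d\n",
              x$stroma_immune_cooc, x$tumour_immune_cooc))
  cat(sprintf("  heterogeneity %.4f bits | contrast %.4f\n",
              x$heterogeneity, x$contrast))
  invisible(x)
}

#' Tidy a slide_features object into a one-row tibble
#'
#' @param x a [slide_features()] object.
#' @param ... unused.
#' @return one-row tibble with the scalar features (CM omitted).
#' @method tidy slide_features
#' @export
tidy.slide_features <- function(x, ...) {
  tibble::tibble(
    stils_count = x$stils_count,
    ttils_count = x$ttils_count,
    total_tils = x$total_tils,
    stils_pct = x$stils_pct,
    stroma_immune_cooc = x$stroma_immune_cooc,
    tumour_immune_cooc = x$tumour_immune_cooc,
    heterogeneity = x$heterogeneity,
    contrast = x$contrast
  )
}

#' Write / read per-slide features as JSON
#'
#' The scalar features are stored as a flat key/value document and the
#' co-occurrence matrix as a labelled matrix; `read_features(write_features(x))`
#' reproduces `x` exactly.
#'
#' @param features a [slide_features()] object.
#' @param path output path (`.json`).
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns a `slide_features` object.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "slide_features"))
  doc <- list(
    stils_count = features$stils_count,
    ttils_count = features$ttils_count,
    total_tils = features$total_tils,
    stils_pct = features$stils_pct,
    stroma_immune_cooc = features$stroma_immune_cooc,
    tumour_immune_cooc = features$tumour_immune_cooc,
    heterogeneity = features$heterogeneity,
    contrast = features$contrast,
    cm = list(
      types = colnames(features$cm),
      counts = unclass(features$cm)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cm <- matrix(as.integer(doc$cm$counts), length(doc$cm$types),
               dimnames = list(doc$cm$types, doc$cm$types))
  slide_features(
    stils_count = doc$stils_count,
    ttils_count = doc$ttils_count,
    total_tils = doc$total_tils,
    stils_pct = doc$stils_pct %||% NA_real_,
    cm = cm,
    heterogeneity = doc$heterogeneity,
    contrast = doc$contrast
  )
}
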