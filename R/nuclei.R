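NUCLEUS_TYPES <- c("tumour", "stromal", "immune", "normal_epithelial", "other")

# common synonyms seen in nuclei-classifier exports; anything else -> other
TYPE_SYNONYMS <- c(
  tumor = "tumour", tumour = "tumour", neoplastic = "tumour",
  stroma = "stromal", stromal = "stromal", connective = "stromal",
  fibroblast = "stromal",
  immune = "immune", lymphocyte = "immune", inflammatory = "immune",
  normal_epithelial = "normal_epithelial", epithelial = "normal_epithelial",
  `non-neoplastic epithelial` = "normal_epithelial",
  other = "other", dead = "other", necrotic = "other"
)

normalise_types <- function(type) {
  raw <- tolower(trimws(as.character(type)))
  mapped <- unname(TYPE_SYNONYMS[raw])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning(sum(unknown), " nucleus label(s) not recognised (",
            paste(unique(raw[unknown]), collapse = ", "),
            "); mapped to 'other'.", call. = FALSE)
    mapped[unknown] <- "other"
  }
  factor(mapped, levels = NUCLEUS_TYPES)
}

validate_nuclei <- function(df) {
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop("Non-numeric or non-finite coordinate at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", ".", call. = FALSE)
  }
  if (any(df$x < 0) || any(df$y < 0)) {
    stop("Nucleus coordinates must be >= 0.", call. = FALSE)
  }
  if (any(!is.na(df$area_px) & df$area_px < 0)) {
    stop("`area_px` must be nonnegative.", call. = FALSE)
  }
  df
}

#' Build a nuclei table
#'
#' The atom of all spatial features: one row per detected nucleus with
#' its centroid in pixel coordinates (`x` = column, `y` = row, both
#' 0-based, `y` increasing downward) and its type. Coordinates live on
#' the same grid as the region masks.
#'
#' @param x,y numeric centroid coordinates (pixels, 0-based).
#' @param type nucleus class labels; recognised classes are `tumour`,
#'   `stromal`, `immune`, `normal_epithelial`, `other` (plus common
#'   synonyms); anything else maps to `other` with a warning.
#' @param area_px optional nonnegative nucleus area in pixels.
#' @param id optional identifiers (default: row number).
#' @return a tibble with columns `id`, `x`, `y`, `nucleus_type`,
#'   `area_px`.
#' @export
nuclei_table <- function(x, y, type, area_px = NA_real_, id = NULL) {
  df <- tibble::tibble(
    id = id %||% seq_along(x),
    x = as.numeric(x),
    y = as.numeric(y),
    nucleus_type = normalise_types(type),
    area_px = as.numeric(area_px)
  )
  validate_nuclei(df)
}

polygon_centroid_area <- function(coords) {
  # shoelace formula; coords is an n x 2 matrix, ring need not be closed
  x <- coords[, 1]
  y <- coords[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1L
  }
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a2 <- sum(cross)
  if (abs(a2) < .Machine$double.eps) {
    return(c(mean(x), mean(y), 0))
  }
  cx <- sum((x + x[j]) * cross) / (3 * a2)
  cy <- sum((y + y[j]) * cross) / (3 * a2)
  c(cx, cy, abs(a2) / 2)
}

read_nuclei_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% stop("GeoJSON file has no 'features' array: ",
                                 path, call. = FALSE)
  rows <- purrr::map(feats, function(f) {
    geom <- f$geometry
    typ <- f$properties$type %||% "other"
    if (identical(geom$type, "Point")) {
      list(x = geom$coordinates[[1]], y = geom$coordinates[[2]],
           type = typ, area = NA_real_)
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      ca <- polygon_centroid_area(coords)
      list(x = ca[1], y = ca[2], type = typ, area = ca[3])
    } else {
      stop("Unsupported geometry type '", geom$type, "' in ", path,
           call. = FALSE)
    }
  })
  nuclei_table(
    x = purrr::map_dbl(rows, "x"),
    y = purrr::map_dbl(rows, "y"),
    type = purrr::map_chr(rows, "type"),
    area_px = purrr::map_dbl(rows, "area")
  )
}

#' Read a nuclei table from disk
#'
#' Accepts a delimited table (CSV/TSV with header columns `x`, `y`,
#' `type` and optional `area`) or a GeoJSON-like FeatureCollection with
#' Point or Polygon geometries and a `type` property. Polygons yield
#' their centroid and polygon area. Row order is preserved.
#'
#' @param path file path.
#' @param format_hint one of `"auto"` (by extension), `"table"`,
#'   `"geojson"`.
#' @return a tibble as from [nuclei_table()].
#' @export
read_nuclei <- function(path, format_hint = c("auto", "table", "geojson")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format_hint == "auto") {
    ext <- tolower(tools::file_ext(path))
    format_hint <- if (ext %in% c("json", "geojson")) "geojson" else "table"
  }
  if (format_hint == "geojson") {
    return(read_nuclei_geojson(path))
  }
  df <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(c("x", "y", "type"), names(df))
  if (length(missing)) {
    stop("Nuclei table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("Non-numeric '", col, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), " of ", path, ".",
             call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  nuclei_table(df$x, df$y, df$type,
               area_px = if ("area" %in% names(df)) df$area else NA_real_,
               id = if ("id" %in% names(df)) df$id else NULL)
}

#' Write a nuclei table as CSV
#'
#' @param nuclei tibble from [nuclei_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_nuclei <- function(nuclei, path) {
  out <- dplyr::transmute(nuclei,
    id = .data$id, x = .data$x, y = .data$y,
    type = as.character(.data$nucleus_type), area = .data$area_px
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
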