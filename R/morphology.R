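#' Binary morphology with exact Euclidean disc structuring elements
#'
#' Masks are logical matrices (row = y, column = x). The structuring
#' element is the closed Euclidean disc: a pixel belongs to the disc of
#' radius `r` iff the distance between pixel centres is `<= r`. Distances
#' are computed with an exact Euclidean distance transform
#' ([EBImage::distmap()]), so results agree pixel-for-pixel with a
#' brute-force union-of-discs construction.
#'
#' @param mask logical matrix; `TRUE` = foreground.
#' @param radius disc radius in pixels, `>= 0`.
#' @return logical matrix of the same dimension.
#' @name morphology
NULL

# squared Euclidean distance of every pixel to the nearest TRUE pixel.
# Exact: squared pixel-grid distances are integers, so the sqrt returned
# by distmap is rounded back without loss.
sq_dist_to <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  if (all(mask)) {
    return(matrix(0, nrow(mask), ncol(mask)))
  }
  d <- EBImage::distmap(EBImage::Image(1 - mask), metric = "euclidean")
  round(EBImage::imageData(d)^2)
}

#' @rdname morphology
#' @export
mask_dilate <- function(mask, radius) {
  mask <- as_binary_matrix(mask)
  assert_scalar_number(radius, "radius", min = 0)
  if (radius == 0 || !any(mask)) {
    return(mask)
  }
  sq_dist_to(mask) <= radius^2
}

#' @rdname morphology
#' @export
mask_erode <- function(mask, radius) {
  mask <- as_binary_matrix(mask)
  assert_scalar_number(radius, "radius", min = 0)
  if (radius == 0 || !any(mask)) {
    return(mask)
  }
  # p survives iff no background pixel lies within radius of p
  sq_dist_to(!mask) > radius^2
}

#' @rdname morphology
#' @export
mask_close <- function(mask, radius) {
  mask_erode(mask_dilate(mask, radius), radius)
}

#' Label 4-connected components of a binary mask
#'
#' Run-based two-pass labelling with union-find. Labels are positive
#' integers in first-encounter (column-major) order; background is 0.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels.
#' @export
label_components <- function(mask) {
  mask <- as_binary_matrix(mask)
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  n_lab <- 0L
  prev_start <- integer(0)
  prev_end <- integer(0)
  prev_lab <- integer(0)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  for (cc in seq_len(W)) {
    col <- mask[, cc]
    if (!any(col)) {
      prev_start <- integer(0)
      next
    }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]
    ends <- ends[keep]
    labs <- integer(length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]
      e <- ends[k]
      lk <- 0L
      if (length(prev_start)) {
        ov <- which(prev_start <= e & prev_end >= s)
        for (o in ov) {
          lo <- find_root(prev_lab[o])
          if (lk == 0L) {
            lk <- lo
          } else if (lo != lk) {
            # union: keep the smaller root
            if (lo < lk) {
              parent[lk] <- lo
              lk <- lo
            } else {
              parent[lo] <- lk
            }
          }
        }
      }
      if (lk == 0L) {
        n_lab <- n_lab + 1L
        parent[n_lab] <- n_lab
        lk <- n_lab
      }
      labs[k] <- lk
      lab[s:e, cc] <- lk
    }
    prev_start <- starts
    prev_end <- ends
    prev_lab <- labs
  }

  if (n_lab == 0L) {
    return(lab)
  }
  roots <- vapply(seq_len(n_lab), find_root, integer(1))
  # renumber roots consecutively in order of first appearance
  final <- match(roots, unique(roots))
  pos <- lab > 0L
  lab[pos] <- final[lab[pos]]
  lab
}

#' Fill holes of a binary mask
#'
#' A hole is a 4-connected background component that does not touch the
#' image border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_matrix(mask)
  if (all(mask) || !any(mask)) {
    return(mask)
  }
  bg <- label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Remove small 4-connected objects
#'
#' @param mask logical matrix.
#' @param min_area minimum pixel area an object must have to be kept.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_area) {
  mask <- as_binary_matrix(mask)
  assert_scalar_number(min_area, "min_area", min = 0)
  if (!any(mask) || min_area <= 1) {
    return(mask)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  lab > 0L & matrix(lab %in% keep, nrow(mask), ncol(mask))
}
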