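# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic helpers do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop("`", name, "` must be > ", min, ".", call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop("`", name, "` must be >= ", min, ".", call. = FALSE)
  }
  invisible(x)
}

# round half up on .5 (base round() is banker's rounding); pinned tie-break
# for pixel lookup of nucleus centroids
round_half_up <- function(x) floor(x + 0.5)

as_binary_matrix <- function(x, name = "mask") {
  if (is.logical(x) && is.matrix(x)) {
    x[is.na(x)] <- FALSE
    return(x)
  }
  if (is.numeric(x) && is.matrix(x)) {
    return(!is.na(x) & x != 0)
  }
  stop("`", name, "` must be a logical or numeric matrix.", call. = FALSE)
}
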