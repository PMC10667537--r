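# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: morphology is done by stamping discs pixel-by-pixel (the
# union-of-discs definition) and hole filling by frontier flood fill;
# co-occurrence by the O(n^2) all-pairs distance matrix.

disc_offsets_lin <- function(r, H) {
  m <- ceiling(r)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ]
  g$dr + g$dc * H
}

# dilation as the union of closed Euclidean discs around foreground pixels
oracle_dilate <- function(mask, r) {
  if (r == 0 || !any(mask)) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  m <- ceiling(r)
  Hp <- H + 2L * m; Wp <- W + 2L * m
  big <- matrix(FALSE, Hp, Wp)
  big[m + seq_len(H), m + seq_len(W)] <- mask
  off <- disc_offsets_lin(r, Hp)
  out <- matrix(FALSE, Hp, Wp)
  for (p in which(big)) out[p + off] <- TRUE
  out[m + seq_len(H), m + seq_len(W)]
}

# erosion by duality with dilation of the complement
oracle_erode <- function(mask, r) {
  if (r == 0 || !any(mask)) return(mask)
  !oracle_dilate(!mask, r)
}

# frontier flood fill of background from the border; unreached background
# components are holes
oracle_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  seeds <- which(!mask &
                   (row(mask) == 1 | row(mask) == H |
                      col(mask) == 1 | col(mask) == W))
  reach[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    rr <- ((frontier - 1L) %% H) + 1L
    cc <- ((frontier - 1L) %/% H) + 1L
    nb <- c(frontier[rr > 1] - 1L, frontier[rr < H] + 1L,
            frontier[cc > 1] - H, frontier[cc < W] + H)
    nb <- unique(nb[!mask[nb] & !reach[nb]])
    reach[nb] <- TRUE
    frontier <- nb
  }
  mask | (!mask & !reach)
}

# full TAS recipe by brute force, mirroring the documented contract
oracle_tas <- function(tumour, stroma, r_dil, r_fill) {
  pad <- ceiling(r_dil + r_fill) + 1L
  H <- nrow(tumour); W <- ncol(tumour)
  big <- matrix(FALSE, H + 2L * pad, W + 2L * pad)
  big[pad + seq_len(H), pad + seq_len(W)] <- tumour
  env <- oracle_dilate(big, r_dil)
  env <- oracle_erode(oracle_dilate(env, r_fill), r_fill)
  env <- oracle_fill_holes(env)
  env[pad + seq_len(H), pad + seq_len(W)] & stroma
}

# all-pairs co-occurrence matrix: the full n x n distance matrix is
# materialised (no spatial index) and every qualifying unordered pair
# tallied through table()
oracle_cm <- function(nuclei, radius, types = c("tumour", "stromal", "immune")) {
  keep <- nuclei$nucleus_type %in% types
  if ("region_label" %in% names(nuclei)) {
    keep <- keep & nuclei$region_label != "excluded"
  }
  x <- nuclei$x[keep]; y <- nuclei$y[keep]
  tp <- as.character(nuclei$nucleus_type[keep])
  K <- length(types)
  cm <- matrix(0L, K, K, dimnames = list(types, types))
  n <- length(x)
  if (n < 2) return(cm)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  hit <- which(upper.tri(d2) & d2 <= radius^2, arr.ind = TRUE)
  if (!nrow(hit)) return(cm)
  a <- tp[hit[, 1]]
  b <- tp[hit[, 2]]
  tab <- table(factor(a, levels = types), factor(b, levels = types))
  for (i in types) {
    for (j in types) {
      if (i == j) {
        cm[i, i] <- cm[i, i] + tab[i, i]
      } else {
        cm[i, j] <- cm[i, j] + tab[i, j] + tab[j, i]
      }
    }
  }
  storage.mode(cm) <- "integer"
  cm
}

# random blobby binary mask (union of discs)
random_blob_mask <- function(H, W, n_blobs, r_range) {
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 0, W - 1); cy <- runif(1, 0, H - 1)
    r <- runif(1, r_range[1], r_range[2])
    m <- m | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  m
}

# random nuclei tibble on a continuous field
random_nuclei <- function(n, extent = 500) {
  nuclei_table(
    x = runif(n, 0, extent),
    y = runif(n, 0, extent),
    type = sample(c("tumour", "stromal", "immune"), n, replace = TRUE)
  )
}

# log partial likelihood for untied right-censored data, single covariate
# (used to grid-search the Cox estimate independently of coxph)
log_partial_lik <- function(beta, time, event, x) {
  o <- order(time)
  time <- time[o]; event <- as.integer(event[o]); x <- x[o]
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
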