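#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the global seed and the stage name, so that changing one stage's
#' name or adding stages never silently reshuffles another stage's stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- as.double(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# fwhm (any unit) -> gaussian sd in the same unit
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# linear voxel index <-> integer (i, j, k) coordinates, 1-based
idx_to_ijk <- function(idx, dim) {
  i <- (idx - 1L) %% dim[1L]
  j <- ((idx - 1L) %/% dim[1L]) %% dim[2L]
  k <- (idx - 1L) %/% (dim[1L] * dim[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_idx <- function(ijk, dim) {
  (ijk[, 3L] - 1L) * dim[1L] * dim[2L] + (ijk[, 2L] - 1L) * dim[1L] + ijk[, 1L]
}

# neighbour offsets for 6/18/26 connectivity on a 3-D lattice
connectivity_offsets <- function(connectivity = 18L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord <= 2,
                 "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

#' Label connected components of a voxel set
#'
#' Breadth-first labeling over the suprathreshold voxels only, so cost
#' scales with the voxel-set size rather than the grid.
#'
#' @param idx Integer vector of linear voxel indices (1-based).
#' @param dim Grid dimensions (length 3).
#' @param connectivity 6, 18 or 26 (default 18, the SPM convention).
#' @return Integer vector of component labels, parallel to `idx`.
#' @export
label_clusters <- function(idx, dim, connectivity = 18L) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  off <- connectivity_offsets(as.integer(connectivity))
  ijk <- idx_to_ijk(idx, dim)
  pos <- match(idx, idx)  # identity; membership tested via fmatch-like match below
  lab <- integer(n)
  cur <- 0L
  # hash from linear index to position in idx
  lookup <- new.env(hash = TRUE, size = n * 2L)
  for (p in seq_len(n)) assign(as.character(idx[p]), p, envir = lookup)
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      here <- ijk[p, ]
      nb <- sweep(off, 2L, here, `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dim[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dim[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dim[3L]
      if (!any(ok)) next
      nidx <- ijk_to_idx(nb[ok, , drop = FALSE], dim)
      for (v in nidx) {
        q <- get0(as.character(v), envir = lookup, ifnotfound = NULL)
        if (!is.null(q) && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# max component size among a voxel set (fast path for permutation nulls)
max_cluster_size <- function(idx, dim, connectivity = 18L) {
  if (length(idx) == 0L) return(0L)
  max(tabulate(label_clusters(idx, dim, connectivity)))
}

# asymptotic Kolmogorov tail: P(sup gap > d) for sample size n
kolmogorov_p <- function(d, n) {
  if (d <= 0) return(1)
  x <- sqrt(n) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
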