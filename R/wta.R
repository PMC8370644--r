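#' Winner-take-all action labeling of suprathreshold voxels
#'
#' A voxel is considered iff it is suprathreshold (one-sided voxel-level
#' p < `forming_p`) in the extension-versus-rest OR the
#' flexion-versus-rest map; its label is the movement with the larger t
#' statistic, so even near-identical t values produce a winner. Exact
#' ties are left unlabeled and counted (a measure-zero event on real
#' data, possible on synthetic data).
#'
#' @param t_ext,t_flex `stat_map`s for the two movement-versus-rest
#'   contrasts, sharing grid and degrees of freedom.
#' @param forming_p Voxel-level threshold (default 0.001).
#' @return A `label_map`: integer array with 0 = unlabeled,
#'   1 = extension, 2 = flexion; attributes `n_ties`, `forming_p`, `df`.
#' @export
wta_labels <- function(t_ext, t_flex, forming_p = 0.001) {
  stopifnot(inherits(t_ext, "stat_map"), inherits(t_flex, "stat_map"))
  if (!identical(dim(t_ext$t), dim(t_flex$t)))
    stop("t maps must share a common grid")
  if (t_ext$df != t_flex$df)
    stop("t maps must share degrees of freedom")
  thr <- forming_threshold(t_ext$df, forming_p, "greater")
  considered <- t_ext$t > thr | t_flex$t > thr
  lab <- array(0L, dim(t_ext$t) %||% length(t_ext$t))
  ties <- considered & t_ext$t == t_flex$t
  lab[considered & t_ext$t > t_flex$t] <- 1L
  lab[considered & t_flex$t > t_ext$t] <- 2L
  structure(lab, n_ties = sum(ties), forming_p = forming_p, df = t_ext$df,
            class = "label_map")
}

label_voxels <- function(map, condition = c("extension", "flexion")) {
  condition <- match.arg(condition)
  which(unclass(map) == if (condition == "extension") 1L else 2L)
}

#' Between-subject label probability map
#'
#' Counts, per voxel and condition, how many subjects carry that label
#' (an integer 0..N, the between-subject probability numerator).
#'
#' @param label_maps List of `label_map`s on a common grid.
#' @return A `probability_map`: list of integer count arrays `extension`
#'   and `flexion` plus `n_subjects`.
#' @export
probability_map <- function(label_maps) {
  dims <- dim(label_maps[[1L]])
  if (!all(vapply(label_maps, function(m) identical(dim(m), dims), logical(1))))
    stop("label maps must share a common grid")
  ext <- array(0L, dims); flex <- array(0L, dims)
  for (m in label_maps) {
    ext <- ext + (unclass(m) == 1L)
    flex <- flex + (unclass(m) == 2L)
  }
  structure(list(extension = ext, flexion = flex,
                 n_subjects = length(label_maps)),
            class = "probability_map")
}

#' Label-consistency histogram within an ROI
#'
#' For k = 1..N subjects, the fraction of ROI voxels whose label count
#' is exactly k, per condition -- the shape of a between-subject
#' consistency histogram scaled as percentage of all ROI voxels.
#'
#' @param pmap A `probability_map`.
#' @param roi Logical mask (non-empty).
#' @return Data frame with `condition`, `k`, `proportion`.
#' @export
wta_histogram <- function(pmap, roi) {
  stopifnot(inherits(pmap, "probability_map"))
  vox <- which(as.vector(roi))
  if (length(vox) == 0L) stop("ROI mask is empty")
  n <- pmap$n_subjects
  out <- lapply(c("extension", "flexion"), function(cond) {
    counts <- pmap[[cond]][vox]
    data.frame(condition = cond, k = seq_len(n),
               proportion = vapply(seq_len(n),
                                   function(k) mean(counts == k), numeric(1)))
  })
  do.call(rbind, out)
}

#' Jaccard similarity of two subjects' label sets
#'
#' `|A intersect B| / |A union B|` over voxels carrying the condition's
#' label; defined as 0 (with a message) when the union is empty.
#'
#' @param a,b `label_map`s on a common grid.
#' @param condition `"extension"` or `"flexion"`.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b, condition = c("extension", "flexion")) {
  condition <- match.arg(condition)
  if (!identical(dim(a), dim(b))) stop("label maps must share a common grid")
  va <- label_voxels(a, condition)
  vb <- label_voxels(b, condition)
  u <- length(union(va, vb))
  if (u == 0L) {
    message("empty union for condition ", condition, "; Jaccard defined as 0")
    return(0)
  }
  length(intersect(va, vb)) / u
}

#' All pairwise Jaccard similarities across subjects
#'
#' @param label_maps List (length >= 2) of `label_map`s.
#' @param roi Optional logical mask restricting the label sets.
#' @param conditions Conditions to tabulate.
#' @return Box-plot-ready data frame: `condition`, `subject_a`,
#'   `subject_b`, `jaccard` -- N(N-1)/2 rows per condition.
#' @export
pairwise_similarity <- function(label_maps, roi = NULL,
                                conditions = c("extension", "flexion")) {
  n <- length(label_maps)
  if (n < 2L) stop("need at least 2 subjects")
  if (!is.null(roi)) {
    keep <- as.vector(roi)
    label_maps <- lapply(label_maps, function(m) {
      x <- unclass(m)
      x[!keep] <- 0L
      structure(x, class = "label_map")
    })
  }
  pairs <- utils::combn(n, 2L)
  out <- lapply(conditions, function(cond) {
    data.frame(condition = cond,
               subject_a = pairs[1L, ], subject_b = pairs[2L, ],
               jaccard = apply(pairs, 2L, function(p) {
                 suppressMessages(jaccard(label_maps[[p[1L]]],
                                          label_maps[[p[2L]]], cond))
               }))
  })
  do.call(rbind, out)
}
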