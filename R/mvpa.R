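#' Extract trial-wise features from detrended runs
#'
#' One feature row per cue: the ROI voxel values of the volume whose
#' acquisition time is nearest to `onset + delay_s` (delay 6 s, i.e.
#' exactly two volumes at TR 3 s), accounting for the time-to-peak of
#' the hemodynamic response. Trials whose target volume is
#' artifact-flagged, or falls beyond the run end, are dropped and
#' logged.
#'
#' @param runs List of `bold_run`s (one subject), or a list of `sim_run`s.
#' @param events_list List of `event_table`s parallel to `runs`.
#' @param roi Logical mask (3-D array) selecting feature voxels.
#' @param delay_s Hemodynamic delay, seconds.
#' @param artifact_reports Optional list of `artifact_report`s parallel
#'   to `runs`.
#' @param detrend If `TRUE` (default), apply the Gaussian running-line
#'   high-pass to the ROI time series before sampling.
#' @param fwhm_trs Running-line width, TRs.
#' @return A `feature_set`: `x` (trials x voxels matrix), `y` (factor
#'   with levels extension/flexion), `voxel` (linear indices of the
#'   columns), `run` (source run per trial), `dropped` (log of removed
#'   trials).
#' @export
extract_features <- function(runs, events_list, roi, delay_s = 6,
                             artifact_reports = NULL, detrend = TRUE,
                             fwhm_trs = 80) {
  if (length(runs) > 0L && inherits(runs[[1L]], "sim_run")) {
    if (missing(events_list) || is.null(events_list))
      events_list <- lapply(runs, `[[`, "events")
    runs <- lapply(runs, `[[`, "bold")
  }
  stopifnot(length(runs) == length(events_list))
  vox <- which(as.vector(roi))
  if (length(vox) == 0L) stop("ROI mask is empty")
  xs <- list(); ys <- list(); rr <- list(); dropped <- list()
  for (r in seq_along(runs)) {
    run <- acquired_frames(runs[[r]])
    ev <- events_list[[r]]
    validate_events(ev)
    tr <- run$tr
    n_vol <- dim(run$data)[4L]
    y <- bold_matrix(run)[, vox, drop = FALSE]
    if (detrend) y <- gaussian_runline_detrend(y, tr, fwhm_trs)
    target <- round((ev$onset + delay_s) / tr) + 1L  # frame times (i-1)*tr
    flagged <- if (is.null(artifact_reports)) integer(0)
               else artifact_reports[[r]]$flags$volume
    late <- target > n_vol
    art <- target %in% flagged & !late
    keep <- !late & !art
    if (any(late))
      warning(sprintf("run %d: %d trial(s) beyond run end dropped", r, sum(late)))
    dropped[[r]] <- data.frame(run = rep(r, sum(!keep)),
                               onset = ev$onset[!keep],
                               reason = ifelse(late[!keep], "beyond_run_end",
                                               "artifact"))
    xs[[r]] <- y[target[keep], , drop = FALSE]
    ys[[r]] <- ev$trial_type[keep]
    rr[[r]] <- rep(r, sum(keep))
  }
  x <- do.call(rbind, xs)
  structure(list(x = x,
                 y = factor(unlist(ys), levels = c("extension", "flexion")),
                 voxel = vox, run = unlist(rr),
                 dropped = do.call(rbind, dropped)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature set: %d trial(s) (%s) x %d voxel(s), %d dropped\n",
              nrow(x$x), paste(table(x$y), collapse = "/"), ncol(x$x),
              nrow(x$dropped)))
  invisible(x)
}

# equal-frequency discretization to `bins` levels (ties broken by order)
ef_bins <- function(x, bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * bins / n)
}

# plug-in MI (bits) between binned feature columns and a binary label
mi_columns <- function(x, y, bins = 4L) {
  n <- nrow(x)
  b <- apply(x, 2L, ef_bins, bins = bins)
  if (is.null(dim(b))) b <- matrix(b, ncol = ncol(x))
  py <- table(y) / n
  mi <- numeric(ncol(x))
  for (cls in levels(y)) {
    rows <- y == cls
    for (k in seq_len(bins)) {
      pj <- colSums(b[rows, , drop = FALSE] == k) / n
      pk <- colSums(b == k) / n
      term <- pj * log2(pj / (pk * as.numeric(py[cls])))
      term[pj == 0] <- 0
      mi <- mi + term
    }
  }
  mi
}

#' Rank voxels by mutual information with the movement label
#'
#' Plug-in mutual information between each feature column, discretized
#' into equal-frequency bins, and the class label; columns are returned
#' in descending MI order, ties broken by ascending voxel index. A
#' constant column has MI 0 by definition.
#'
#' @param features A `feature_set`, or a list with `x` and `y`.
#' @param bins Number of equal-frequency bins (default 4).
#' @return Data frame with `column`, `voxel`, `mi` (bits), sorted.
#' @export
mutual_information_rank <- function(features, bins = 4L) {
  x <- features$x; y <- features$y
  if (min(table(y)) < 2L) stop("need at least 2 trials per class")
  const <- apply(x, 2L, function(v) max(v) == min(v))
  mi <- mi_columns(x, y, bins)
  mi[const] <- 0
  ord <- order(-mi, seq_len(ncol(x)))
  data.frame(column = ord,
             voxel = (features$voxel %||% seq_len(ncol(x)))[ord],
             mi = mi[ord])
}

#' Retain the top-ranked features up to a cap
#'
#' @param ranked Output of [mutual_information_rank()].
#' @param max_features Feature cap (default 2000).
#' @return Integer vector of retained column indices, a prefix of the
#'   ranked order of length `min(max_features, n_columns)`.
#' @export
select_features <- function(ranked, max_features = 2000L) {
  ranked$column[seq_len(min(max_features, nrow(ranked)))]
}

confusion_metrics <- function(truth, pred, positive = "extension") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = 100 * (tp + tn) / max(tp + tn + fp + fn, 1L),
       sensitivity = 100 * tp / max(tp + fn, 1L),
       specificity = 100 * tn / max(tn + fp, 1L))
}

#' Cross-validated linear SVM classification of the two movements
#'
#' Trials are partitioned into `k` stratified folds with a seeded
#' shuffle. Inside each training fold -- and only there, so no test-set
#' information leaks -- voxels are ranked by mutual information, the top
#' `max_features` are retained, features are standardized by
#' training-fold statistics, and a linear SVM (cost `cost`) is trained;
#' the held-out fold is then predicted. Extension is the positive class
#' for sensitivity/specificity, and ROC AUC is computed from the pooled
#' decision values with a fixed direction (so a null classifier sits at
#' 0.5).
#'
#' @param features A `feature_set`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold partition.
#' @param max_features Per-fold feature cap (default 2000).
#' @param bins MI discretization bins.
#' @param cost SVM regularization constant (default 1).
#' @return A `cv_result`: pooled `accuracy`, `sensitivity`,
#'   `specificity` (percent), `auc`, `confusion`, per-fold metric table,
#'   fold assignments and per-fold selected features.
#' @export
cross_validate_svm <- function(features, k = 10L, seed = 1L,
                               max_features = 2000L, bins = 4L, cost = 1) {
  x <- features$x; y <- features$y
  n <- nrow(x)
  if (min(table(y)) < k) stop("need at least k trials per class")
  set.seed(seed)
  fold <- integer(n)
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  dv <- numeric(n)
  per_fold <- vector("list", k)
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    tr_fs <- list(x = x[tr_idx, , drop = FALSE], y = droplevels(y[tr_idx]),
                  voxel = features$voxel)
    ranked <- mutual_information_rank(tr_fs, bins = bins)
    keep <- select_features(ranked, max_features)
    selected[[f]] <- (features$voxel %||% seq_len(ncol(x)))[keep]
    mu <- colMeans(x[tr_idx, keep, drop = FALSE])
    sd <- apply(x[tr_idx, keep, drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    std <- function(m) sweep(sweep(m, 2L, mu), 2L, sd, `/`)
    fit <- e1071::svm(std(x[tr_idx, keep, drop = FALSE]), y[tr_idx],
                      kernel = "linear", cost = cost, scale = FALSE)
    p <- stats::predict(fit, std(x[te_idx, keep, drop = FALSE]),
                        decision.values = TRUE)
    d <- drop(attr(p, "decision.values"))
    # orient decision values so larger means "extension"
    if (colnames(attr(p, "decision.values"))[1L] == "flexion/extension")
      d <- -d
    pred[te_idx] <- p
    dv[te_idx] <- d
    per_fold[[f]] <- data.frame(fold = f,
                                as.data.frame(confusion_metrics(y[te_idx], p)))
  }
  pooled <- confusion_metrics(y, pred)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = dv,
                                        levels = c("flexion", "extension"),
                                        direction = "<", quiet = TRUE)))
  structure(list(accuracy = pooled$accuracy, sensitivity = pooled$sensitivity,
                 specificity = pooled$specificity, auc = auc,
                 confusion = pooled[c("tp", "tn", "fp", "fn")],
                 per_fold = do.call(rbind, per_fold),
                 fold = fold, decision_values = dv, predicted = pred,
                 selected = selected, positive_class = "extension",
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
              x$k, x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Classification sweep over regions of interest
#'
#' Runs the full classification arm in each ROI and in the union of all
#' ROIs (always appended), for one subject.
#'
#' @param runs List of `bold_run`s or `sim_run`s for one subject.
#' @param events_list List of `event_table`s (taken from `sim_run`s when
#'   omitted).
#' @param rois Named list of logical masks; empty ROIs are skipped with
#'   a warning.
#' @param seed Integer seed (fold partitions are derived per ROI name so
#'   identical masks give identical folds).
#' @param ... Passed to [extract_features()] and [cross_validate_svm()]
#'   (`k`, `max_features`, `delay_s`, ...).
#' @return List with `table` (per-ROI accuracy/sensitivity/specificity/
#'   AUC data frame) and `results` (named list of `cv_result`s).
#' @export
roi_sweep <- function(runs, events_list = NULL, rois, seed = 1L, ...) {
  dots <- list(...)
  ex_args <- dots[names(dots) %in% names(formals(extract_features))]
  cv_args <- dots[names(dots) %in% names(formals(cross_validate_svm))]
  keep <- vapply(rois, any, logical(1))
  if (any(!keep)) {
    warning("skipping empty ROI(s): ", paste(names(rois)[!keep], collapse = ", "))
    rois <- rois[keep]
  }
  rois <- c(rois, list(union = Reduce(`|`, rois)))
  results <- lapply(names(rois), function(nm) {
    fs <- do.call(extract_features,
                  c(list(runs = runs, events_list = events_list,
                         roi = rois[[nm]]), ex_args))
    do.call(cross_validate_svm, c(list(features = fs, seed = seed), cv_args))
  })
  names(results) <- names(rois)
  tab <- data.frame(roi = names(rois),
                    n_voxels = vapply(rois, sum, numeric(1)),
                    accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
                    sensitivity = vapply(results, `[[`, numeric(1), "sensitivity"),
                    specificity = vapply(results, `[[`, numeric(1), "specificity"),
                    auc = vapply(results, `[[`, numeric(1), "auc"),
                    row.names = NULL)
  list(table = tab, results = results)
}

#' Across-subject classification summary table
#'
#' @param sweeps List of [roi_sweep()] outputs, one per subject.
#' @return Long per-subject data frame plus per-ROI mean (SD) accuracy,
#'   the shape of a regional accuracy report.
#' @export
mvpa_summary <- function(sweeps) {
  per <- do.call(rbind, lapply(seq_along(sweeps), function(s) {
    d <- sweeps[[s]]$table
    d$subject <- s
    d
  }))
  agg <- do.call(rbind, lapply(split(per, per$roi), function(d) {
    data.frame(roi = d$roi[1L], mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy),
               mean_auc = mean(d$auc))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(-agg$mean_accuracy), ]
  list(per_subject = per, summary = agg)
}
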