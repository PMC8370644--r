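toy_features <- function(x, y) {
  structure(list(x = x, y = factor(y, levels = c("extension", "flexion")),
                 voxel = seq_len(ncol(x)), run = rep(1L, nrow(x)),
                 dropped = data.frame()), class = "feature_set")
}

test_that("feature volumes sit at onset + delay, nearest frame", {
  # onset 30 s, delay 6 s, TR 3 s -> volume at t = 36 s (index 13, 1-based)
  truth <- make_ground_truth(small_truth_params(), 1L, seed = 1)[[1L]]
  ev <- make_design(small_design(1L), seed = 1)[[1L]]
  sr <- simulate_run(ev, truth, quiet_noise(white_sd = 0, drift_amp = 0),
                     seed = 1)
  roi <- array(FALSE, dim(truth$amp_ext)); roi[1:4] <- TRUE
  marker <- sr$bold
  marker$data[1, 1, 1, ] <- seq_len(116) * 1000   # frame index beacon
  fs <- extract_features(list(marker), list(ev), roi, detrend = FALSE)
  got <- unname(fs$x[, 1L] / 1000)
  expect_equal(got, round((ev$onset + 6) / 3) + 1)
  # onset 30 s, delay 6 s, TR 3 s -> the volume acquired at t = 36 s
  one <- ev[1L, , drop = FALSE]
  one$onset <- 30
  attributes(one)[c("blocks", "rests", "tr", "n_volumes", "n_dummy")] <-
    attributes(ev)[c("blocks", "rests", "tr", "n_volumes", "n_dummy")]
  class(one) <- class(ev)
  fs1 <- extract_features(list(marker), list(one), roi, detrend = FALSE)
  expect_equal(unname(fs1$x[1L, 1L] / 1000), 13)
})

test_that("four clean default runs yield 120 trials; flagged trials drop", {
  truth <- make_ground_truth(small_truth_params(), 1L, seed = 1)[[1L]]
  spec <- small_design(4L)
  runs <- simulate_subject(spec, truth, quiet_noise(), seed = 2)
  roi <- truth$rois$M1
  fs <- extract_features(runs, roi = roi)
  expect_equal(nrow(fs$x), 120L)
  expect_equal(as.vector(table(fs$y)), c(60L, 60L))
  # flag every volume of run 1: its 30 trials drop, both labels remain
  rep1 <- structure(list(flags = data.frame(volume = 1:116, reason = "global_z"),
                         n_volumes = 116L), class = "artifact_report")
  none <- structure(list(flags = data.frame(volume = integer(0),
                                            reason = character(0)),
                         n_volumes = 116L), class = "artifact_report")
  fs2 <- extract_features(runs, roi = roi,
                          artifact_reports = list(rep1, none, none, none))
  expect_equal(nrow(fs2$x), 90L)
  expect_equal(nrow(fs2$dropped), 30L)
  expect_true(all(c("extension", "flexion") %in% fs2$y))
})

test_that("mutual information matches an exhaustive joint-histogram oracle", {
  set.seed(5)
  n <- 20L; bins <- 4L
  x <- matrix(stats::rnorm(n * 6), n, 6)
  y <- factor(rep(c("extension", "flexion"), each = 10),
              levels = c("extension", "flexion"))
  ranked <- mutual_information_rank(toy_features(x, y), bins = bins)
  # oracle: explicit joint-count table per column, plug-in MI in bits
  for (j in 1:6) {
    b <- ceiling(rank(x[, j], ties.method = "first") * bins / n)
    tab <- table(factor(b, levels = 1:bins), y)
    p <- tab / n
    mi_ref <- 0
    for (r in 1:bins) for (cc in 1:2) {
      if (p[r, cc] > 0)
        mi_ref <- mi_ref + p[r, cc] *
          log2(p[r, cc] / (sum(p[r, ]) * sum(p[, cc])))
    }
    expect_equal(ranked$mi[ranked$column == j], mi_ref, tolerance = 1e-12)
  }
})

test_that("MI is 1 bit for a label-identical feature and 0 for a constant", {
  y <- rep(c("extension", "flexion"), each = 10)
  x <- cbind(ifelse(y == "extension", 1, 0) + 0.001 * seq_len(20),  # separable
             rep(3.7, 20))                                          # constant
  ranked <- mutual_information_rank(toy_features(x, y), bins = 2L)
  expect_equal(ranked$mi[ranked$column == 1L], 1, tolerance = 1e-12)
  expect_equal(ranked$mi[ranked$column == 2L], 0)
  expect_equal(ranked$column[1L], 1L)
})

test_that("ranking sorts by MI with index tie-breaks; cap selects a prefix", {
  set.seed(6)
  x <- matrix(stats::rnorm(40 * 30), 40, 30)
  x[, 30] <- x[, 2]                       # exact duplicate -> tied MI
  y <- rep(c("extension", "flexion"), 20)
  ranked <- mutual_information_rank(toy_features(x, y))
  expect_true(all(diff(ranked$mi) <= 1e-12))
  tied <- ranked$column[ranked$mi == ranked$mi[ranked$column == 2L]]
  expect_lt(which(tied == 2L), which(tied == 30L))   # ascending index on ties
  expect_equal(select_features(ranked, 10L), ranked$column[1:10])
  expect_equal(length(select_features(ranked, 2000L)), 30L)
  expect_equal(length(select_features(ranked, 7L)), 7L)
})

test_that("confusion-count metrics follow their formulas", {
  m <- wristbold:::confusion_metrics(
    truth = factor(c(rep("extension", 10), rep("flexion", 10))),
    pred = factor(c(rep("extension", 9), "flexion",
                    rep("flexion", 8), rep("extension", 2))))
  expect_equal(m[c("tp", "tn", "fp", "fn")], list(tp = 9, tn = 8, fp = 2, fn = 1))
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
})

test_that("perfectly separable features classify at 100%", {
  set.seed(7)
  y <- rep(c("extension", "flexion"), each = 30)
  x <- matrix(stats::rnorm(60 * 50), 60, 50)
  x[y == "extension", 1:10] <- x[y == "extension", 1:10] + 10  # disjoint supports
  cv <- cross_validate_svm(toy_features(x, y), k = 10, seed = 1)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$auc, 1)
})

test_that("stratified folds partition trials and results are seed-deterministic", {
  set.seed(8)
  y <- rep(c("extension", "flexion"), each = 25)
  x <- matrix(stats::rnorm(50 * 20), 50, 20)
  fs <- toy_features(x, y)
  cv1 <- cross_validate_svm(fs, k = 5, seed = 3)
  cv2 <- cross_validate_svm(fs, k = 5, seed = 3)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$auc, cv2$auc)
  expect_equal(sort(unique(cv1$fold)), 1:5)
  for (f in 1:5)
    expect_equal(as.vector(table(y[cv1$fold == f])), c(5L, 5L))
  expect_error(cross_validate_svm(toy_features(x[1:12, ], y[c(1:6, 26:31)]),
                                  k = 10), "at least k")
})

test_that("label permutation yields chance-level accuracy and AUC", {
  # features carry real class signal; permuting labels must erase it
  truth <- make_ground_truth(
    small_truth_params(amp_unique_ext = 2, amp_unique_flex = 2), 1L,
    seed = 1)[[1L]]
  runs <- simulate_subject(small_design(2L), truth, quiet_noise(), seed = 3)
  fs <- extract_features(runs, roi = truth$rois$M1)
  accs <- aucs <- numeric(8)
  for (i in seq_along(accs)) {
    set.seed(100 + i)
    fsp <- fs
    fsp$y <- sample(fs$y)
    cv <- cross_validate_svm(fsp, seed = i)
    accs[i] <- cv$accuracy; aucs[i] <- cv$auc
  }
  expect_gt(mean(accs), 42); expect_lt(mean(accs), 58)
  expect_gt(mean(aucs), 0.40); expect_lt(mean(aucs), 0.60)
})

test_that("localized discriminative signal is detected where it lives", {
  # ROI holding the unique clusters beats a distal ROI with none
  tp <- small_truth_params(amp_unique_ext = 2, amp_unique_flex = 2,
                           subject_jitter_sd = 0)
  truth <- make_ground_truth(tp, 1L, seed = 1)[[1L]]
  runs <- simulate_subject(small_design(4L), truth,
                           quiet_noise(white_sd = 5), seed = 4)
  sw <- roi_sweep(runs, rois = truth$rois[c("M1", "S1", "PMd")], seed = 1)
  tab <- sw$table
  expect_gt(tab$accuracy[tab$roi == "M1"], tab$accuracy[tab$roi == "PMd"])
  expect_gt(tab$accuracy[tab$roi == "M1"], 55)
  # identical masks give identical results under the same seed
  sw2 <- roi_sweep(runs, rois = list(a = truth$rois$M1, b = truth$rois$M1),
                   seed = 5)
  expect_equal(sw2$table$accuracy[1L], sw2$table$accuracy[2L])
  # union row is always appended and is at least as large as any single ROI
  expect_true("union" %in% sw$table$roi)
  expect_gte(tab$n_voxels[tab$roi == "union"], max(tab$n_voxels[1:3]))
})
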