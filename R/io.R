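#' Read and write BOLD runs as NIfTI-1
#'
#' Grid geometry, voxel size and TR (stored in the 4th pixdim slot) are
#' preserved round-trip; both plain `.nii` and gzipped `.nii.gz` files
#' are accepted.
#'
#' @param path File path.
#' @param run A `bold_run`.
#' @param ... Unused.
#' @return `read_bold()` returns a `bold_run`; `write_bold()` returns
#'   `path` invisibly.
#' @export
read_bold <- function(path, ...) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4-D BOLD image, got ", length(d), "-D: ", path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 4L || pd[4L] <= 0)
    stop("missing or invalid TR in NIfTI header: ", path)
  bold_run(array(as.vector(img), d), tr = pd[4L], voxel_size = pd[1:3])
}

#' @rdname read_bold
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size, run$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write event tables as BIDS-style events.tsv
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`; onsets
#' in seconds from the first acquired (non-dummy) volume. On read,
#' block annotations are reconstructed from runs of consecutive
#' same-condition cues, and rest annotations from the gaps between them
#' (plus the leading rest), so downstream block-level analyses work on
#' re-imported designs.
#'
#' @param path File path.
#' @param events An `event_table`.
#' @param tr,n_volumes Sampling metadata attached on read.
#' @return `read_events()` returns an `event_table`; `write_events()`
#'   returns `path` invisibly.
#' @export
read_events <- function(path, tr = 3, n_volumes = 116L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_events(df)
  grp <- cumsum(c(TRUE, df$trial_type[-1L] != df$trial_type[-nrow(df)]))
  blocks <- do.call(rbind, lapply(split(df, grp), function(d) {
    data.frame(start = d$onset[1L],
               end = d$onset[nrow(d)] + d$duration[nrow(d)],
               condition = d$trial_type[1L])
  }))
  rownames(blocks) <- NULL
  rests <- data.frame(start = c(0, blocks$end),
                      end = c(blocks$start, n_volumes * tr))
  rests <- rests[rests$end > rests$start, ]
  structure(df, blocks = blocks, rests = rests, tr = tr,
            n_volumes = as.integer(n_volumes),
            class = c("event_table", "data.frame"))
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events[, c("onset", "duration", "trial_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a motion-parameter trace as 6-column text
#'
#' @param motion `n_volumes` x 6 matrix.
#' @param path File path.
#' @return `path`, invisibly; `read_motion()` returns the matrix.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' Full pipeline configuration
#'
#' Bundles the parameter blocks of every stage with a global seed; each
#' stochastic stage derives its own seed from the global seed and the
#' stage name via [derive_seed()]. The configuration round-trips
#' losslessly through JSON.
#'
#' @param n_subjects Number of simulated subjects.
#' @param design,truth,noise Stage parameter objects (or lists of
#'   overrides for their constructors).
#' @param glm,mvpa,wta,dominance Named lists of stage options.
#' @param seed Global integer seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(n_subjects = 10L, design = design_spec(),
                            truth = truth_params(), noise = noise_spec(),
                            glm = list(forming_p = 0.001, alpha = 0.05,
                                       n_perm = 500L, smooth_fwhm_mm = 6),
                            mvpa = list(k = 10L, max_features = 2000L,
                                        delay_s = 6),
                            wta = list(forming_p = 0.001),
                            dominance = list(forming_p = 0.001),
                            seed = 1L) {
  as_block <- function(x, ctor) {
    if (is.list(x) && !inherits(x, c("design_spec", "truth_params", "noise_spec")))
      x <- do.call(ctor, x)
    x
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 design = as_block(design, design_spec),
                 truth = as_block(truth, truth_params),
                 noise = as_block(noise, noise_spec),
                 glm = glm, mvpa = mvpa, wta = wta, dominance = dominance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- lapply(config, function(b) if (is.object(b)) unclass(b) else b)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$design <- do.call(design_spec, x$design)
  x$truth$shared_centers <- matrix(x$truth$shared_centers, ncol = 3L)
  x$truth <- do.call(truth_params, x$truth)
  x$noise <- do.call(noise_spec, x$noise)
  do.call(pipeline_config, x)
}
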