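#' Specify the mixed blocked/event wrist-movement design
#'
#' One run holds two task blocks (one per movement), each a series of
#' `cues_per_block` visually cued movements at pseudo-random onset
#' asynchronies drawn from `soa_menu`, flanked by rest periods, with an
#' instruction period before each block during which the forearm posture
#' is adopted. Defaults reproduce the study design this package targets:
#' 15-cue blocks, SOAs of 6/8/10 s, 15 s rests, TR 3 s, 4 dummy + 116
#' acquired volumes per 6-minute run.
#'
#' @param n_runs Number of runs per subject.
#' @param cues_per_block Cued movements per block; must be a multiple of
#'   `length(soa_menu)` so the SOA multiset can be exactly balanced.
#' @param soa_menu Stimulus onset asynchronies in seconds.
#' @param rest_duration Rest before/after each block, seconds.
#' @param instruction_duration Posture-instruction period, seconds;
#'   unmodeled in the signal (treated as rest baseline).
#' @param tr Repetition time, seconds.
#' @param n_volumes Acquired (analysed) volumes per run.
#' @param n_dummy Discarded steady-state volumes at run start.
#' @param hold_duration Seconds the movement end-point is held; cues are
#'   modeled as boxcars of this width.
#' @return A validated `design_spec` object.
#' @export
design_spec <- function(n_runs = 4L, cues_per_block = 15L,
                        soa_menu = c(6, 8, 10), rest_duration = 15,
                        instruction_duration = 9, tr = 3,
                        n_volumes = 116L, n_dummy = 4L,
                        hold_duration = 1) {
  if (any(soa_menu <= 0)) stop("soa_menu values must be strictly positive")
  if (cues_per_block %% length(soa_menu) != 0L)
    stop("cues_per_block must be a multiple of length(soa_menu) for a balanced SOA multiset")
  if (tr <= 0 || n_volumes < 2L || n_runs < 1L)
    stop("invalid design dimensions")
  spec <- structure(list(
    n_runs = as.integer(n_runs), cues_per_block = as.integer(cues_per_block),
    soa_menu = as.numeric(soa_menu), rest_duration = rest_duration,
    instruction_duration = instruction_duration, tr = tr,
    n_volumes = as.integer(n_volumes), n_dummy = as.integer(n_dummy),
    hold_duration = hold_duration), class = "design_spec")
  block_len <- cues_per_block * mean(soa_menu)  # sum of the balanced multiset
  scheduled <- rest_duration +
    2 * (instruction_duration + block_len + rest_duration)
  if (scheduled > n_volumes * tr)
    stop(sprintf("schedule overflow: %.0f s of events do not fit in %.0f s of acquisition",
                 scheduled, n_volumes * tr))
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("wrist-movement design: %d run(s), 2 x %d cues, SOA {%s} s, TR %g s, %d+%d volumes\n",
              x$n_runs, x$cues_per_block, paste(x$soa_menu, collapse = ", "),
              x$tr, x$n_dummy, x$n_volumes))
  invisible(x)
}

new_event_table <- function(df, blocks, rests, spec) {
  structure(df,
            blocks = blocks, rests = rests,
            tr = spec$tr, n_volumes = spec$n_volumes, n_dummy = spec$n_dummy,
            class = c("event_table", "data.frame"))
}

#' Generate per-run event tables for a design
#'
#' Each run contains exactly one extension block and one flexion block.
#' Per block, the SOA sequence is a seeded shuffle of a balanced multiset
#' (equal counts of each `soa_menu` value, i.e. 5 x 6 s, 5 x 8 s and
#' 5 x 10 s under defaults, whose mean is 8 s exactly). The first cue
#' falls at block start; the k-th drawn SOA separates cue k from cue
#' k+1, the last one forming tail room before the following rest. Block
#' condition order alternates extension-first / flexion-first across
#' runs. Residual run time is appended to the final rest.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @return A list of `event_table` data frames (columns `onset`,
#'   `duration`, `trial_type`; onsets in seconds from the first acquired
#'   volume), one per run, each carrying `blocks` and `rests` interval
#'   annotations as attributes.
#' @export
make_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  multiset <- rep(spec$soa_menu, each = spec$cues_per_block / length(spec$soa_menu))
  run_end <- spec$n_volumes * spec$tr
  lapply(seq_len(spec$n_runs), function(r) {
    first <- if (r %% 2L == 1L) "extension" else "flexion"
    conds <- c(first, setdiff(c("extension", "flexion"), first))
    t0 <- spec$rest_duration
    rows <- list(); blocks <- list()
    rests <- list(data.frame(start = 0, end = spec$rest_duration))
    for (b in 1:2) {
      soa <- sample(multiset)
      start <- t0 + spec$instruction_duration
      onsets <- start + cumsum(c(0, soa[-length(soa)]))
      end <- start + sum(soa)
      rows[[b]] <- data.frame(onset = onsets, duration = spec$hold_duration,
                              trial_type = conds[b])
      blocks[[b]] <- data.frame(start = start, end = end, condition = conds[b])
      rest_end <- if (b == 2L) run_end else end + spec$rest_duration
      rests[[b + 1L]] <- data.frame(start = end, end = rest_end)
      t0 <- end + spec$rest_duration
    }
    new_event_table(do.call(rbind, rows),
                    blocks = do.call(rbind, blocks),
                    rests = do.call(rbind, rests), spec)
  })
}

#' Interval annotations of an event table
#'
#' @param events An `event_table`.
#' @return `event_blocks()`: data frame of block start/end/condition;
#'   `event_rests()`: data frame of rest start/end (the final rest
#'   absorbs residual run time).
#' @export
event_blocks <- function(events) attr(events, "blocks")

#' @rdname event_blocks
#' @export
event_rests <- function(events) attr(events, "rests")

validate_events <- function(events) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events))) stop("events must have onset, duration, trial_type")
  if (is.unsorted(events$onset, strictly = TRUE)) stop("event onsets must be strictly increasing")
  bad <- which(!events$trial_type %in% c("extension", "flexion"))
  if (length(bad) > 0L)
    stop(sprintf("unknown condition '%s' in events row %d", events$trial_type[bad[1L]], bad[1L]))
  invisible(events)
}
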