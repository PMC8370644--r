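#' Run the full four-arm analysis pipeline
#'
#' Simulates a multi-subject dataset, then runs artifact
#' detection/exclusion, the univariate GLM arm (subject t maps, group
#' maps with permutation cluster correction, ROI activation volumes),
#' the classification arm (per-subject ROI sweep), winner-take-all
#' labeling (probability maps, consistency histograms, pairwise
#' Jaccard), and percent-signal-change dominance (run consistency
#' against the binomial null with KS tests). Writes per-stage CSV/JSON
#' outputs, group NIfTI maps, a markdown report and a manifest that
#' records the configuration hash, derived seeds, package version and
#' the checksum of every output file. Identical `(config, seed)` give
#' identical manifests and numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param write_bold_runs Also write every simulated run as NIfTI
#'   (large; off by default).
#' @param verbose Log stage progress and wall time to `log.txt` and the
#'   console.
#' @return Invisibly, a list with the per-stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, write_bold_runs = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (verbose) message(msg)
  }
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-10s done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }
  seeds <- sapply(c("truth", "design", "mvpa", "glm_perm"),
                  function(s) derive_seed(config$seed, s))

  sim <- stage("simulate", {
    ds <- simulate_dataset(config$design, config$truth, config$noise,
                           config$n_subjects, seed = config$seed)
    write_config(config, file.path(out_dir, "config.json"))
    add_file(file.path(out_dir, "config.json"))
    if (write_bold_runs) {
      for (s in seq_len(config$n_subjects)) for (r in seq_along(ds$subjects[[s]])) {
        p <- file.path(out_dir, sprintf("sub-%02d_run-%02d_bold.nii.gz", s, r))
        write_bold(ds$subjects[[s]][[r]]$bold, p); add_file(p)
        pe <- file.path(out_dir, sprintf("sub-%02d_run-%02d_events.tsv", s, r))
        write_events(ds$subjects[[s]][[r]]$events, pe); add_file(pe)
        pm <- file.path(out_dir, sprintf("sub-%02d_run-%02d_motion.txt", s, r))
        write_motion(ds$subjects[[s]][[r]]$motion, pm); add_file(pm)
      }
    }
    ds
  })
  rois <- sim$truth[[1L]]$rois

  prep <- stage("preprocess", {
    reports <- lapply(sim$subjects, function(runs)
      lapply(runs, function(sr) detect_artifacts(sr$bold, sr$motion)))
    excl <- exclude_runs(reports)
    tab <- do.call(rbind, lapply(seq_along(excl), function(s) {
      d <- excl[[s]]; d$subject <- s; d
    }))
    p <- file.path(out_dir, "exclusions.csv")
    utils::write.csv(tab, p, row.names = FALSE); add_file(p)
    list(reports = reports, exclusions = excl, table = tab)
  })

  glm_res <- stage("glm", {
    fwhm <- config$glm$smooth_fwhm_mm %||% 0
    per_subject <- lapply(seq_len(config$n_subjects), function(s) {
      runs <- sim$subjects[[s]]
      kept <- which(!prep$exclusions[[s]]$excluded)
      if (length(kept) == 0L) return(NULL)
      ys <- list(); xs <- list()
      for (r in kept) {
        sr <- runs[[r]]
        bold <- sr$bold
        if (fwhm > 0) {
          d <- dim(bold$data)
          for (t in seq_len(d[4L]))
            bold$data[, , , t] <- smooth_spatial(bold$data[, , , t], fwhm,
                                                 bold$voxel_size)
        }
        ys[[length(ys) + 1L]] <- bold_matrix(bold)
        xs[[length(xs) + 1L]] <- build_design_matrix(
          sr$events, motion = sr$motion,
          artifact_report = prep$reports[[s]][[r]])$X
      }
      # concatenated-run fit with run-blocked confounds
      X <- block_design(xs)
      fit <- fit_glm(do.call(rbind, ys), X)
      fit$geom <- list(dim = config$truth$grid_shape,
                       voxel_size = rep(config$truth$voxel_size, 3L))
      tmaps <- lapply(c("ext>rest", "flex>rest", "ext>flex"), function(cn) {
        cv <- numeric(ncol(X)); names(cv) <- colnames(X)
        cv["extension"] <- if (cn != "flex>rest") 1 else 0
        cv["flexion"] <- switch(cn, "flex>rest" = 1, "ext>flex" = -1, 0)
        m <- contrast_tmap(fit, cv)
        m$contrast <- cn
        m$alternative <- if (cn == "ext>flex") "two.sided" else "greater"
        m
      })
      names(tmaps) <- c("ext>rest", "flex>rest", "ext>flex")
      eff <- lapply(names(tmaps), function(cn) {
        cv <- contrast_named(colnames(X), cn)
        array(drop(cv %*% fit$coef), config$truth$grid_shape)
      })
      names(eff) <- names(tmaps)
      list(tmaps = tmaps, effects = eff)
    })
    keep <- !vapply(per_subject, is.null, logical(1))
    group <- lapply(c("ext>rest", "flex>rest", "ext>flex"), function(cn) {
      maps <- lapply(per_subject[keep], function(p) p$effects[[cn]])
      cl <- cluster_threshold(
        forming_p = config$glm$forming_p, alpha = config$glm$alpha,
        n_perm = config$glm$n_perm, seed = derive_seed(config$seed, "glm_perm"),
        subject_maps = maps)
      gt <- group_ttest(maps, contrast = cn,
                        alternative = if (cn == "ext>flex") "two.sided" else "greater",
                        voxel_size = config$truth$voxel_size)
      list(map = gt, clusters = cl)
    })
    names(group) <- c("ext>rest", "flex>rest", "ext>flex")
    for (cn in names(group)) {
      p <- file.path(out_dir, sprintf("group_%s_tmap.nii.gz",
                                      gsub(">", "_gt_", cn)))
      m <- group[[cn]]$map
      write_bold(bold_run(array(m$t, c(dim(m$t), 1L)), tr = 1,
                          voxel_size = config$truth$voxel_size), p)
      add_file(p)
    }
    vol <- activation_volume_table(
      lapply(per_subject[keep], function(p) p$tmaps[["ext>rest"]]), rois,
      config$glm$forming_p)
    volf <- activation_volume_table(
      lapply(per_subject[keep], function(p) p$tmaps[["flex>rest"]]), rois,
      config$glm$forming_p)
    vtab <- merge(vol$summary, volf$summary, by = "roi",
                  suffixes = c("_extension", "_flexion"))
    p <- file.path(out_dir, "roi_activation_volumes.csv")
    utils::write.csv(vtab, p, row.names = FALSE); add_file(p)
    ctab <- do.call(rbind, lapply(names(group), function(cn) {
      cl <- group[[cn]]$clusters$clusters
      if (nrow(cl) == 0L) return(NULL)
      cbind(contrast = cn, cl)
    }))
    p <- file.path(out_dir, "group_clusters.csv")
    utils::write.csv(ctab %||% data.frame(), p, row.names = FALSE); add_file(p)
    list(per_subject = per_subject, group = group, volumes = vtab)
  })

  mvpa_res <- stage("mvpa", {
    sweeps <- lapply(seq_len(config$n_subjects), function(s) {
      roi_sweep(sim$subjects[[s]], rois = rois,
                seed = derive_seed(config$seed, paste0("mvpa", s)),
                artifact_reports = prep$reports[[s]],
                k = config$mvpa$k, max_features = config$mvpa$max_features,
                delay_s = config$mvpa$delay_s)
    })
    summ <- mvpa_summary(sweeps)
    p <- file.path(out_dir, "mvpa_accuracy.csv")
    utils::write.csv(summ$per_subject, p, row.names = FALSE); add_file(p)
    p <- file.path(out_dir, "mvpa_summary.csv")
    utils::write.csv(summ$summary, p, row.names = FALSE); add_file(p)
    list(sweeps = sweeps, summary = summ)
  })

  wta_res <- stage("wta", {
    labels <- lapply(glm_res$per_subject, function(ps) {
      if (is.null(ps)) return(NULL)
      wta_labels(ps$tmaps[["ext>rest"]], ps$tmaps[["flex>rest"]],
                 config$wta$forming_p)
    })
    labels <- labels[!vapply(labels, is.null, logical(1))]
    pmap <- probability_map(labels)
    hist <- do.call(rbind, lapply(names(rois), function(nm)
      cbind(roi = nm, wta_histogram(pmap, rois[[nm]]))))
    p <- file.path(out_dir, "wta_histograms.csv")
    utils::write.csv(hist, p, row.names = FALSE); add_file(p)
    jac <- if (length(labels) >= 2L)
      do.call(rbind, lapply(names(rois), function(nm)
        cbind(roi = nm, pairwise_similarity(labels, rois[[nm]]))))
    else NULL
    if (!is.null(jac)) {
      p <- file.path(out_dir, "wta_jaccard.csv")
      utils::write.csv(jac, p, row.names = FALSE); add_file(p)
    }
    list(labels = labels, pmap = pmap, histogram = hist, jaccard = jac)
  })

  dom_res <- stage("dominance", {
    out <- lapply(seq_len(config$n_subjects), function(s) {
      ps <- glm_res$per_subject[[s]]
      if (is.null(ps)) return(NULL)
      supra <- array(FALSE, config$truth$grid_shape)
      supra[suprathreshold_idx(ps$tmaps[["ext>rest"]],
                               config$dominance$forming_p)] <- TRUE
      supra[suprathreshold_idx(ps$tmaps[["flex>rest"]],
                               config$dominance$forming_p)] <- TRUE
      if (!any(supra)) return(list(active = 0L))
      kept <- which(!prep$exclusions[[s]]$excluded)
      psc <- lapply(sim$subjects[[s]][kept], psc_maps, active_mask = supra)
      cons <- if (length(psc) >= 2L)
        run_consistency(lapply(psc, preference_labels)) else NULL
      list(active = sum(supra), psc = psc,
           session = session_average(psc), consistency = cons,
           ks = if (!is.null(cons)) ks_vs_binomial(cons) else NULL)
    })
    tab <- do.call(rbind, lapply(seq_along(out), function(s) {
      o <- out[[s]]
      data.frame(subject = s, n_active = o$active %||% 0L,
                 ks_statistic = o$ks$statistic %||% NA_real_,
                 ks_p = o$ks$p_value %||% NA_real_)
    }))
    p <- file.path(out_dir, "dominance_ks.csv")
    utils::write.csv(tab, p, row.names = FALSE); add_file(p)
    list(per_subject = out, table = tab)
  })

  manifest <- stage("report", {
    rp <- file.path(out_dir, "report.md")
    write_report(rp, config, prep, glm_res, mvpa_res, wta_res, dom_res)
    add_file(rp)
    cfg_json <- jsonlite::toJSON(lapply(unclass(config), function(b)
      if (is.object(b)) unclass(b) else b), auto_unbox = TRUE, digits = NA)
    man <- list(package = "wristbold",
                version = as.character(utils::packageVersion("wristbold")),
                r_version = paste(R.version$major, R.version$minor, sep = "."),
                seed = config$seed, stage_seeds = as.list(seeds),
                config_hash = unname(md5_string(cfg_json)),
                files = lapply(sort(unique(files)), function(f)
                  list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(sim = sim, preprocess = prep, glm = glm_res,
                 mvpa = mvpa_res, wta = wta_res, dominance = dom_res,
                 manifest = manifest, out_dir = out_dir))
}

md5_string <- function(x) {
  f <- tempfile()
  writeLines(as.character(x), f)
  on.exit(unlink(f))
  tools::md5sum(f)
}

# stack per-run design matrices into one blocked design: task and motion
# columns are shared, confounds (spikes, dct, intercept) become
# run-specific blocks
block_design <- function(xs) {
  n_runs <- length(xs)
  if (n_runs == 1L) return(xs[[1L]])
  shared_cols <- c("extension", "flexion")
  out <- list()
  for (r in seq_len(n_runs)) {
    x <- xs[[r]]
    shared <- x[, shared_cols, drop = FALSE]
    rest <- x[, setdiff(colnames(x), shared_cols), drop = FALSE]
    colnames(rest) <- paste0("run", r, "_", colnames(rest))
    out[[r]] <- list(shared = shared, rest = rest)
  }
  shared <- do.call(rbind, lapply(out, `[[`, "shared"))
  rests <- lapply(out, `[[`, "rest")
  nr <- vapply(rests, nrow, integer(1))
  nc <- vapply(rests, ncol, integer(1))
  conf <- matrix(0, sum(nr), sum(nc))
  colnames(conf) <- unlist(lapply(rests, colnames))
  at_r <- cumsum(c(0L, nr)); at_c <- cumsum(c(0L, nc))
  for (r in seq_len(n_runs))
    conf[(at_r[r] + 1L):at_r[r + 1L], (at_c[r] + 1L):at_c[r + 1L]] <- rests[[r]]
  cbind(shared, conf)
}

contrast_named <- function(labels, cn) {
  cv <- numeric(length(labels)); names(cv) <- labels
  cv["extension"] <- if (cn != "flex>rest") 1 else 0
  cv["flexion"] <- switch(cn, "flex>rest" = 1, "ext>flex" = -1, 0)
  cv
}

write_report <- function(path, config, prep, glm_res, mvpa_res, wta_res,
                         dom_res) {
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines <- c(
    "# Wrist extension vs flexion: four-arm analysis report", "",
    sprintf("Subjects: %d; runs/subject: %d; grid %s at %g mm; seed %d.",
            config$n_subjects, config$design$n_runs,
            paste(config$truth$grid_shape, collapse = "x"),
            config$truth$voxel_size, config$seed), "",
    "## Run exclusions", "", md_table(prep$table), "",
    "## GLM: ROI activation volumes (mm^3)", "", md_table(glm_res$volumes), "",
    "## GLM: group cluster inference", "")
  for (cn in names(glm_res$group)) {
    cl <- glm_res$group[[cn]]$clusters
    lines <- c(lines, sprintf(
      "- `%s`: %d cluster(s), %d surviving FWE correction; critical extent %s mm^3",
      cn, nrow(cl$clusters), sum(cl$clusters$survives),
      format(cl$critical_extent_mm3)))
  }
  lines <- c(lines, "", "## MVPA: regional classification accuracy", "",
             md_table(mvpa_res$summary$summary), "",
             "## Winner-take-all: between-subject consistency", "",
             md_table(utils::head(wta_res$histogram[
               order(-wta_res$histogram$proportion), ], 12L)), "")
  if (!is.null(wta_res$jaccard)) {
    jag <- stats::aggregate(jaccard ~ roi + condition, wta_res$jaccard, stats::median)
    names(jag)[3L] <- "median_jaccard"
    lines <- c(lines, sprintf("Pairwise Jaccard (%d pair(s) per condition per ROI):",
                              choose(length(wta_res$labels), 2)), "",
               md_table(jag), "")
  }
  lines <- c(lines, "## Dominance: run-to-run consistency vs binomial null", "",
             md_table(dom_res$table), "")
  writeLines(lines, path)
}
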