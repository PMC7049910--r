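#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end phantom pipeline: cohort
#' size, acquisition geometry, kinetics, sampling plan, descriptor
#' toggles and parameters, and output options.  All randomness flows
#' from the single `seed`, from which each stage derives a fixed
#' substream (covariates/truth, template placement, per-subject series
#' noise), so a config + seed pair fully determines every output.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param geometry An `acq_geometry`.
#' @param kinetics A [kinetics_model()].
#' @param covariates A [covariate_model()].
#' @param plan Sampling plan (see [default_sampling_plan()]).
#' @param descriptors Subset of `c("Enh", "RPS", "GLCM", "ULBP",
#'   "LCP")`; AUEC and Slope scalars are always computed.
#' @param units Optional character filter of region units as
#'   `"tissue@tier"` (e.g. `"WM@middle-high"`); `NULL` keeps all.
#' @param cube_side DFT cube side for the radial power spectrum.
#' @param grey_levels GLCM grey levels.
#' @param lbp_radius LBP/LCP radius (voxels).
#' @param M FPCA components per descriptor element.
#' @param enhancement_percent Express enhancement in percent.
#' @param idm_printed_form See [haralick_features()].
#' @param run_stats Run the clinical-association stage.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 6L, seed = 1L,
                            geometry = phantom_geometry(),
                            kinetics = kinetics_model(),
                            covariates = covariate_model(),
                            plan = default_sampling_plan(),
                            descriptors = c("Enh", "RPS", "GLCM",
                                            "ULBP", "LCP"),
                            units = NULL,
                            cube_side = 64L, grey_levels = 16L,
                            lbp_radius = 1L, M = 5L,
                            enhancement_percent = FALSE,
                            idm_printed_form = FALSE,
                            run_stats = TRUE, out_dir = NULL) {
  known <- c("Enh", "RPS", "GLCM", "ULBP", "LCP")
  bad <- setdiff(descriptors, known)
  if (length(bad))
    stop(sprintf("unknown descriptor(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), geometry = geometry,
                 kinetics = kinetics, covariates = covariates,
                 plan = plan, descriptors = descriptors, units = units,
                 cube_side = as.integer(cube_side),
                 grey_levels = as.integer(grey_levels),
                 lbp_radius = as.integer(lbp_radius), M = as.integer(M),
                 enhancement_percent = enhancement_percent,
                 idm_printed_form = idm_printed_form,
                 run_stats = run_stats, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar keys map directly to [pipeline_config()] arguments; nested
#' `geometry` and `kinetics` blocks override the corresponding
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$geometry))
    args$geometry <- do.call(acquisition_geometry, y$geometry)
  if (!is.null(y$kinetics))
    args$kinetics <- do.call(kinetics_model, y$kinetics)
  scalars <- intersect(names(y), c("n_subjects", "seed", "descriptors",
                                   "units", "cube_side", "grey_levels",
                                   "lbp_radius", "M",
                                   "enhancement_percent",
                                   "idm_printed_form", "run_stats",
                                   "out_dir"))
  args[scalars] <- y[scalars]
  do.call(pipeline_config, args)
}

# stable key for a (descriptor, unit) cell
cell_key <- function(descriptor, tissue, tier)
  paste(descriptor, paste0(tissue, "@", tier), sep = "|")

#' Compute all descriptor trajectories for one subject
#'
#' The "describe" stage of the pipeline: for every region unit,
#' extracts the voxel stack and computes the configured descriptor
#' trajectories (features x frames) plus the AUEC and post-peak slope
#' scalars.
#'
#' @param series A `dce_series`.
#' @param template A `sampling_template` on the same geometry.
#' @param config A [pipeline_config()] carrying descriptor settings.
#' @param units Data.frame of region units (default: all units of the
#'   template, filtered by `config$units`).
#' @return List with `trajectories` (named list, one `descriptor|unit`
#'   matrix per cell), `scalars` (data.frame `tier`, `tissue`, `auec`,
#'   `slope`) and `failures` (character).
#' @export
describe_subject <- function(series, template, config = pipeline_config(),
                             units = NULL) {
  if (is.null(units)) {
    units <- region_units(template)
    if (!is.null(config$units))
      units <- units[paste0(units$tissue, "@", units$tier) %in%
                       config$units, , drop = FALSE]
  }
  t_min <- frame_times(series$geometry, "min")
  texture_on <- any(c("GLCM", "ULBP", "LCP") %in% config$descriptors)
  traj <- list(); failures <- character()
  scal <- list()
  for (u in seq_len(nrow(units))) {
    tier <- as.character(units$tier[u]); tissue <- units$tissue[u]
    ukey <- paste0(tissue, "@", tier)
    stack <- extract_region_stack(series, template, tier, tissue)
    curve <- enhancement_curve(stack, times = t_min,
                               percent = config$enhancement_percent)
    scal[[u]] <- data.frame(tier = tier, tissue = tissue,
                            auec = auec(curve),
                            slope = tryCatch(enhancement_slope(curve),
                                             error = function(e) NA_real_),
                            stringsAsFactors = FALSE)
    if ("Enh" %in% config$descriptors)
      traj[[cell_key("Enh", tissue, tier)]] <-
        matrix(as.numeric(curve), nrow = 1L,
               dimnames = list("enh", NULL))
    if ("RPS" %in% config$descriptors) {
      res <- tryCatch(rps_trajectory_from_stack(stack, config$cube_side),
                      error = identity)
      if (inherits(res, "error"))
        failures <- c(failures, sprintf("RPS %s: %s", ukey,
                                        conditionMessage(res)))
      else traj[[cell_key("RPS", tissue, tier)]] <- res
    }
    if (texture_on) {
      res <- tryCatch(
        texture_trajectories(series, template, tier, tissue,
                             grey_levels = config$grey_levels,
                             lbp_radius = config$lbp_radius,
                             idm_printed_form = config$idm_printed_form),
        error = identity)
      if (inherits(res, "error"))
        failures <- c(failures, sprintf("texture %s: %s", ukey,
                                        conditionMessage(res)))
      else for (d in intersect(c("GLCM", "ULBP", "LCP"),
                               config$descriptors))
        traj[[cell_key(d, tissue, tier)]] <- res[[d]]
    }
  }
  list(trajectories = traj, scalars = do.call(rbind, scal),
       failures = failures)
}

#' Reduce descriptor trajectories to first-mode scores
#'
#' Applies the four-step multivariate FPCA to one (unit, descriptor)
#' cell.  When the cohort is too small to support `M` components per
#' element, `M` is reduced to `min(M, P - 1, T)` with a warning so
#' small smoke runs still complete.
#'
#' @param traj 3D array, subjects x frames x features.
#' @param times Frame times in minutes.
#' @param M Requested components per element.
#' @return List with `scores` and `explained_var`.
#' @export
reduce_scores <- function(traj, times, M = 5L) {
  P <- dim(traj)[1L]; Tn <- dim(traj)[2L]
  M_eff <- min(M, P - 1L, Tn)
  if (M_eff < M)
    warning(sprintf("M reduced from %d to %d (P = %d, T = %d)",
                    M, M_eff, P, Tn), call. = FALSE)
  fit <- mfpca(traj, times = times, M = M_eff)
  list(scores = fit$scores, explained_var = fit$explained_var)
}

#' Run the full phantom pipeline
#'
#' Generates a synthetic cohort, builds the sampling template, computes
#' the selected descriptor trajectories plus AUEC and post-peak slope
#' for every region unit, reduces trajectories to first-mode FPCA
#' scores, and relates all scores to the clinical covariates.  A
#' failure confined to one (unit, descriptor) cell is recorded and
#' skipped rather than aborting the run.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with `covariates`,
#'   `template`, `units`, `trajectories` (named list of subject x frame
#'   x feature arrays), `score_table` (long data.frame), `validation`
#'   (from [run_validation()], or `NULL`), `failures`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  geometry <- config$geometry
  cohort <- phantom_cohort(config$n_subjects, seed = seed,
                           kinetics = config$kinetics,
                           model = config$covariates)
  labels <- build_label_map(geometry)
  template <- build_template(labels, geometry, plan = config$plan,
                             seed = seed + 2L)
  units <- region_units(template)
  if (!is.null(config$units)) {
    keep <- paste0(units$tissue, "@", units$tier) %in% config$units
    units <- units[keep, , drop = FALSE]
    if (nrow(units) == 0L) stop("unit filter removed every region unit",
                                call. = FALSE)
  }
  t_min <- frame_times(geometry, "min")
  P <- config$n_subjects
  Tn <- geometry$n_frames
  traj <- list()
  scalars <- list()
  failures <- character()
  for (i in seq_len(P)) {
    ph <- generate_series(cohort$truths[[i]], geometry, config$kinetics,
                          seed = (seed + 10000L + i) %% 2147483647L)
    desc <- describe_subject(ph$series, template, config, units)
    failures <- c(failures, desc$failures)
    for (key in names(desc$trajectories)) {
      mat <- desc$trajectories[[key]]
      if (is.null(traj[[key]]))
        traj[[key]] <- array(NA_real_, c(P, Tn, nrow(mat)),
                             dimnames = list(NULL, NULL, rownames(mat)))
      traj[[key]][i, , ] <- t(mat)
    }
    scalars[[i]] <- cbind(subject_id = cohort$covariates$subject_id[i],
                          desc$scalars, stringsAsFactors = FALSE)
  }
  scalars <- do.call(rbind, scalars)
  rows <- list()
  for (key in names(traj)) {
    parts <- strsplit(key, "[|@]")[[1L]]
    red <- tryCatch(reduce_scores(traj[[key]], t_min, config$M),
                    error = identity)
    if (inherits(red, "error")) {
      failures <- c(failures, sprintf("reduce %s: %s", key,
                                      conditionMessage(red)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = cohort$covariates$subject_id,
      tier = parts[3L], tissue = parts[2L], descriptor = parts[1L],
      score = red$scores, explained_var = red$explained_var,
      stringsAsFactors = FALSE)
  }
  score_table <- do.call(rbind, c(rows, list(
    data.frame(subject_id = scalars$subject_id, tier = scalars$tier,
               tissue = scalars$tissue, descriptor = "AUEC",
               score = scalars$auec, explained_var = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(subject_id = scalars$subject_id, tier = scalars$tier,
               tissue = scalars$tissue, descriptor = "Slope",
               score = scalars$slope, explained_var = NA_real_,
               stringsAsFactors = FALSE))))
  validation <- if (isTRUE(config$run_stats))
    run_validation(score_table[!is.na(score_table$score), ],
                   cohort$covariates) else NULL
  result <- structure(list(covariates = cohort$covariates,
                           template = template, units = units,
                           trajectories = traj,
                           score_table = score_table,
                           validation = validation,
                           failures = failures, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subjects, %d region units, %d descriptor cells\n",
              nrow(x$covariates), nrow(x$units), length(x$trajectories)))
  if (length(x$failures))
    cat(sprintf("  %d cell failure(s), e.g. %s\n", length(x$failures),
                x$failures[1L]))
  invisible(x)
}

# CSV with a reproducibility comment header (seed + config checksum)
write_result_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write pipeline outputs to the configured directory
#'
#' Emits `covariates.csv`, `template.json`, `scores.csv`,
#' `kw_results.csv`, `regression_results.csv` and a `config.json`
#' sidecar.  Every CSV starts with a comment line carrying the seed and
#' the MD5 checksum of the config sidecar, so outputs are traceable to
#' the exact configuration (read them back with `comment.char = "#"`).
#'
#' @param result A `pipeline_result` whose config has `out_dir` set.
#' @return Invisibly, the output directory.
#' @export
write_pipeline_result <- function(result) {
  dir <- result$config$out_dir
  stopifnot(!is.null(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_json <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(n_subjects = cfg$n_subjects, seed = cfg$seed,
         geometry = unclass(cfg$geometry),
         descriptors = cfg$descriptors, units = cfg$units,
         cube_side = cfg$cube_side, grey_levels = cfg$grey_levels,
         lbp_radius = cfg$lbp_radius, M = cfg$M,
         enhancement_percent = cfg$enhancement_percent,
         idm_printed_form = cfg$idm_printed_form),
    cfg_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  meta <- sprintf("# seed=%d config_md5=%s", cfg$seed,
                  unname(tools::md5sum(cfg_json)))
  write_result_csv(result$covariates, file.path(dir, "covariates.csv"),
                   meta)
  write_result_csv(result$score_table, file.path(dir, "scores.csv"),
                   meta)
  write_template(result$template, file.path(dir, "template.json"))
  if (!is.null(result$validation)) {
    write_result_csv(result$validation$kw,
                     file.path(dir, "kw_results.csv"), meta)
    write_result_csv(result$validation$regression,
                     file.path(dir, "regression_results.csv"), meta)
  }
  invisible(dir)
}

#' Serialise / reload descriptor trajectories
#'
#' Long-format CSV interchange (`subject`, `frame`, `feature`, `value`
#' per cell) written at full precision, so downstream stages re-run
#' from the cached trajectories reproduce the original scores exactly.
#'
#' @param trajectories Named list of subject x frame x feature arrays
#'   (as in a `pipeline_result`).
#' @param path CSV file path.
#' @return `write_trajectories` invisibly returns `path`;
#'   `read_trajectories` returns the named list of arrays.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(names(trajectories), function(key) {
    a <- trajectories[[key]]
    d <- dim(a)
    idx <- expand.grid(subject = seq_len(d[1L]), frame = seq_len(d[2L]),
                       feature = seq_len(d[3L]))
    data.frame(cell = key, idx,
               value = sprintf("%.17g", as.numeric(a)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(df$cell)) {
    sub <- df[df$cell == key, ]
    d <- c(max(sub$subject), max(sub$frame), max(sub$feature))
    a <- array(NA_real_, d)
    a[cbind(sub$subject, sub$frame, sub$feature)] <- as.numeric(sub$value)
    out[[key]] <- a
  }
  out
}
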