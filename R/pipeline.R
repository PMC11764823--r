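#' One cell of the stratified analysis grid
#'
#' A configuration fixes the window width, the eating-label criterion
#' (united or intersected), the raw-data source (full = both wrists,
#' dominant = dominant wrist only) and the forest settings.
#'
#' @param width_s Window width in seconds (1-5).
#' @param label_criterion \code{"united"} or \code{"intersected"}.
#' @param source_mode \code{"full"} or \code{"dominant"}.
#' @param step_s Window step in seconds (default 1).
#' @param n_trees,cv_folds,seed Forest settings (defaults 500, 5, 1).
#' @return Object of class \code{analysis_config}.
#' @export
analysis_config <- function(width_s,
                            label_criterion = c("united", "intersected"),
                            source_mode = c("dominant", "full"),
                            step_s = 1, n_trees = 500, cv_folds = 5,
                            seed = 1) {
  label_criterion <- match.arg(label_criterion)
  source_mode <- match.arg(source_mode)
  structure(list(width_s = as.integer(width_s),
                 label_criterion = label_criterion,
                 source_mode = source_mode, step_s = as.integer(step_s),
                 n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> %s source, %s labels, %d s windows (step %d s), %d trees, %d-fold CV, seed %d\n",
              x$source_mode, x$label_criterion, x$width_s, x$step_s,
              x$n_trees, x$cv_folds, x$seed))
  invisible(x)
}

#' The default 20-cell analysis grid
#'
#' All combinations of the five window widths, the two label criteria and
#' the two raw-data sources: 5 x 2 x 2 = 20 stratified analyses.
#'
#' @param widths Window widths (default 1:5).
#' @param criteria Label criteria (default united and intersected).
#' @param sources Raw-data sources (default full and dominant).
#' @param step_s,n_trees,cv_folds,seed Shared settings for every cell.
#' @return List of \code{\link{analysis_config}} objects, one per cell.
#' @examples
#' length(default_grid())  # 20
#' @export
default_grid <- function(widths = 1:5,
                         criteria = c("united", "intersected"),
                         sources = c("full", "dominant"),
                         step_s = 1, n_trees = 500, cv_folds = 5, seed = 1) {
  cells <- expand.grid(width_s = widths, label_criterion = criteria,
                       source_mode = sources, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    analysis_config(cells$width_s[i], cells$label_criterion[i],
                    cells$source_mode[i], step_s = step_s,
                    n_trees = n_trees, cv_folds = cv_folds, seed = seed)
  })
}

# ---- kinetic CSV dialect ----------------------------------------------------

.KINETIC_COLS <- c("subject_id", "wrist", "segment_id", "food_id", "t_s",
                   "x_mG", "y_mG", "z_mG")

#' Read and write the kinetic CSV dialect
#'
#' UTF-8 comma-separated raw streams, one row per 5 Hz sample, header
#' required: \code{subject_id, wrist (dominant|nondominant), segment_id,
#' food_id, t_s, x_mG, y_mG, z_mG}. Reading validates the header, requires
#' timestamps strictly increasing within each (subject, wrist) stream, and
#' reports gaps from the nominal spacing via a message.
#'
#' @param path CSV file path.
#' @param streams Data frame in the dialect above (e.g. a simulated meal's
#'   wrist streams stacked together).
#' @param sample_rate_hz Nominal rate used for gap detection (default 5).
#' @return \code{read_kinetic_csv} returns the validated data frame;
#'   \code{write_kinetic_csv} returns \code{path} invisibly.
#' @export
read_kinetic_csv <- function(path, sample_rate_hz = 5) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       wrist = "character",
                                       segment_id = "character",
                                       food_id = "character"))
  missing_cols <- setdiff(.KINETIC_COLS, names(df))
  if (length(missing_cols)) {
    stop("kinetic CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$subject_id, df$wrist)
  for (k in unique(key)) {
    rows <- which(key == k)
    dt <- diff(df$t_s[rows])
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop("non-monotone timestamps for stream ", k, " at row ",
           rows[bad[1] + 1])
    }
    gaps <- sum(dt > 1.5 / sample_rate_hz)
    if (gaps > 0) {
      message("stream ", k, ": ", gaps, " gap(s) larger than the nominal ",
              1 / sample_rate_hz, " s spacing")
    }
  }
  df[.KINETIC_COLS]
}

#' @rdname read_kinetic_csv
#' @export
write_kinetic_csv <- function(streams, path) {
  missing_cols <- setdiff(.KINETIC_COLS, names(streams))
  if (length(missing_cols)) {
    stop("stream table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- streams[.KINETIC_COLS]
  # %.17g makes the decimal text round-trip doubles exactly, so a written
  # study re-read from disk reproduces the in-memory analysis bit for bit
  for (v in c("t_s", "x_mG", "y_mG", "z_mG")) {
    out[[v]] <- sprintf("%.17g", out[[v]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write or read a whole synthetic study as plain-text files
#'
#' Serialises a simulated study into a directory: \code{kinetics.csv} (all
#' subjects and wrists in the kinetic CSV dialect), \code{annotations.json}
#' (both evaluators' intervals plus the ground-truth intervals under
#' evaluator \code{"truth"}), \code{audio.csv} (per-subject 25 FPS envelope:
#' \code{subject_id, frame, level}) and \code{meta.json}.
#'
#' @param study An \code{\link{simulate_study}} result.
#' @param dir Output directory (created if needed).
#' @return \code{write_study} returns \code{dir} invisibly;
#'   \code{read_study} returns an \code{eating_study} object.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "eating_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  streams <- do.call(rbind, lapply(study$subjects, function(s)
    rbind(s$meal$streams$dominant, s$meal$streams$nondominant)))
  write_kinetic_csv(streams, file.path(dir, "kinetics.csv"))

  ann <- do.call(rbind, lapply(study$subjects, function(s) {
    truth <- s$meal$truth
    truth$evaluator <- "truth"
    rbind(s$annotations$a$intervals, s$annotations$b$intervals,
          truth[, c("segment_id", "food_id", "start_s", "stop_s",
                    "evaluator")])
  }))
  rownames(ann) <- NULL
  write_annotations(ann, file.path(dir, "annotations.json"))

  audio <- do.call(rbind, lapply(names(study$subjects), function(id) {
    env <- study$subjects[[id]]$meal$audio_envelope
    data.frame(subject_id = id, frame = seq_along(env),
               level = sprintf("%.17g", as.numeric(env)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(audio, file.path(dir, "audio.csv"), row.names = FALSE,
                   quote = FALSE)

  meta <- list(n_subjects = study$n_subjects,
               effect_size = study$effect_size,
               duration_per_item_s = study$duration_per_item_s,
               jitter_sd_s = study$jitter_sd_s,
               sample_rate_hz = study$sample_rate_hz,
               seed = study$seed,
               audio_t0_s = .AUDIO_T0_S, audio_rate_fps = 25,
               menus = vapply(study$subjects, `[[`, "", "menu"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  streams <- read_kinetic_csv(file.path(dir, "kinetics.csv"),
                              meta$sample_rate_hz)
  ann <- read_annotations(file.path(dir, "annotations.json"))
  audio <- utils::read.csv(file.path(dir, "audio.csv"),
                           stringsAsFactors = FALSE)
  ids <- unique(streams$subject_id)
  subjects <- lapply(ids, function(id) {
    sub <- streams[streams$subject_id == id, ]
    env <- audio$level[audio$subject_id == id]
    attr(env, "t0_s") <- meta$audio_t0_s
    attr(env, "rate_fps") <- meta$audio_rate_fps
    sub_ann <- ann[ann$segment_id %in% unique(sub$segment_id), ]
    truth <- sub_ann[sub_ann$evaluator == "truth",
                     c("segment_id", "food_id", "start_s", "stop_s")]
    rownames(truth) <- NULL
    dom <- sub[sub$wrist == "dominant", ]
    rownames(dom) <- NULL
    nond <- sub[sub$wrist == "nondominant", ]
    rownames(nond) <- NULL
    track <- function(ev) {
      iv <- sub_ann[sub_ann$evaluator == ev, ]
      rownames(iv) <- NULL
      structure(list(evaluator_id = ev, intervals = iv, labels = NULL),
                class = "annotation_track")
    }
    meal <- structure(list(
      streams = list(dominant = dom, nondominant = nond),
      truth = truth, audio_envelope = env,
      clap_times_s = unname(tapply(dom$t_s, dom$segment_id, min)[
        unique(dom$segment_id)]),
      segments = unique(dom[, c("segment_id", "food_id")]),
      audio_offset_s = NA_real_, sample_rate_hz = meta$sample_rate_hz,
      subject_id = id, seed = meta$seed
    ), class = "synthetic_meal")
    list(meal = meal, annotations = list(a = track("a"), b = track("b")),
         menu = unname(meta$menus[id]))
  })
  names(subjects) <- ids
  structure(list(subjects = subjects, n_subjects = length(ids),
                 effect_size = meta$effect_size,
                 duration_per_item_s = meta$duration_per_item_s,
                 jitter_sd_s = meta$jitter_sd_s,
                 sample_rate_hz = meta$sample_rate_hz, seed = meta$seed),
            class = "eating_study")
}

# ---- orchestration ----------------------------------------------------------

# Per-subject kinetic frames, per-segment clock offsets and fused labels.
# Criterion- and width-independent, so a grid run does this once.
.prepare_study <- function(study) {
  lapply(study$subjects, function(s) {
    meal <- s$meal
    dom <- derive_kinetics(meal$streams$dominant)
    nond <- derive_kinetics(meal$streams$nondominant)
    offsets <- segment_offsets(meal$streams$dominant, meal$audio_envelope,
                               study$sample_rate_hz)
    # Evaluator intervals live on the camera clock; rasterise them through
    # the per-segment offsets recovered from the claps.
    a <- rasterize_intervals(s$annotations$a$intervals, dom$t_s,
                             offset_s = offsets)
    b <- rasterize_intervals(s$annotations$b$intervals, dom$t_s,
                             offset_s = offsets)
    list(frames = list(dominant = dom, nondominant = nond),
         fused = combine_labels(a, b), offsets = offsets)
  })
}

# IU table for one width across all subjects (always full-source features;
# dominant mode keeps the dominant wrist's columns).
.study_ius <- function(prep, spec) {
  do.call(rbind, lapply(prep, function(p)
    build_ius(p$frames, p$fused, spec, source_mode = "full")))
}

.cell_iu_table <- function(ius_full, config) {
  if (config$source_mode == "dominant") {
    keep <- !grepl("^nondominant_", names(ius_full))
    ius_full[, keep]
  } else {
    ius_full
  }
}

.fit_cell <- function(iu_table, config) {
  eating_col <- paste0("eating_", config$label_criterion)
  eating <- iu_table[iu_table[[eating_col]], ]
  settings <- forest_settings(
    n_trees = config$n_trees, cv_folds = config$cv_folds,
    seed = split_seed(config$seed, config$source_mode,
                      config$label_criterion, config$width_s)
  )
  model <- food_forest(eating, settings)
  structure(list(
    config = config, n_ius = nrow(iu_table), n_eating = nrow(eating),
    n_features = ncol(model$x), chosen_mtry = model$mtry,
    cv_accuracy = model$cv, metrics = oob_metrics(model),
    importances = scaled_importance(model)
  ), class = "stratified_result")
}

#' Run one stratified analysis
#'
#' Executes the full pipeline for a single grid cell: kinetic-variable
#' derivation on both wrists, clap-based per-segment clock alignment,
#' annotation fusion into united/intersected per-sample labels, IU
#' construction at the configured width, then CV mtry selection, the final
#' forest on all eating IUs, OOB one-vs-all metrics and scaled Gini
#' importance.
#'
#' @param study An \code{\link{simulate_study}} (or \code{\link{read_study}})
#'   object.
#' @param config An \code{\link{analysis_config}}.
#' @return Object of class \code{stratified_result}: list with
#'   \code{config}, \code{n_ius}, \code{n_eating}, \code{n_features},
#'   \code{chosen_mtry}, \code{cv_accuracy}, \code{metrics} (per-food OOB
#'   sensitivity/specificity/support) and \code{importances}.
#' @export
run_stratified_analysis <- function(study, config) {
  stopifnot(inherits(study, "eating_study"),
            inherits(config, "analysis_config"))
  prep <- .prepare_study(study)
  spec <- window_spec(config$width_s, config$step_s, study$sample_rate_hz)
  ius <- .study_ius(prep, spec)
  .fit_cell(.cell_iu_table(ius, config), config)
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("<stratified_result> %s/%s, width %d s: %d IUs (%d eating), mtry %d\n",
              x$config$source_mode, x$config$label_criterion,
              x$config$width_s, x$n_ius, x$n_eating, x$chosen_mtry))
  cat(sprintf("  mean OOB sensitivity %.3f, specificity %.3f over %d foods\n",
              mean(x$metrics$sensitivity, na.rm = TRUE),
              mean(x$metrics$specificity, na.rm = TRUE), nrow(x$metrics)))
  invisible(x)
}

#' Run the full stratified analysis grid
#'
#' Runs every cell of the width x criterion x source grid (20 cells by
#' default) on one study, sharing the kinetics/sync/label preparation across
#' cells. Optionally writes the three result CSVs (\code{summary.csv},
#' \code{results.csv} with one row per cell and food, \code{importance.csv}
#' with one row per cell and variable) to \code{out_dir}.
#'
#' @param study An \code{eating_study}.
#' @param widths,criteria,sources Grid axes (defaults give the 20-cell
#'   grid).
#' @param step_s,n_trees,cv_folds,seed Shared cell settings.
#' @param keep_going Continue past a failing cell (its error is recorded)?
#'   Default FALSE: any cell failure aborts the grid.
#' @param out_dir Optional directory for the result CSVs.
#' @return Object of class \code{analysis_grid}: list of
#'   \code{stratified_result}s plus a \code{summary} data frame.
#' @export
run_full_grid <- function(study, widths = 1:5,
                          criteria = c("united", "intersected"),
                          sources = c("full", "dominant"),
                          step_s = 1, n_trees = 500, cv_folds = 5,
                          seed = 1, keep_going = FALSE, out_dir = NULL) {
  stopifnot(inherits(study, "eating_study"))
  configs <- default_grid(widths, criteria, sources, step_s = step_s,
                          n_trees = n_trees, cv_folds = cv_folds,
                          seed = seed)
  prep <- .prepare_study(study)
  ius_by_width <- list()
  results <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    wkey <- as.character(cfg$width_s)
    if (is.null(ius_by_width[[wkey]])) {
      spec <- window_spec(cfg$width_s, cfg$step_s, study$sample_rate_hz)
      ius_by_width[[wkey]] <- .study_ius(prep, spec)
    }
    res <- if (keep_going) {
      tryCatch(.fit_cell(.cell_iu_table(ius_by_width[[wkey]], cfg), cfg),
               error = function(e) {
                 warning("grid cell (", cfg$source_mode, ", ",
                         cfg$label_criterion, ", ", cfg$width_s,
                         " s) failed: ", conditionMessage(e))
                 structure(list(config = cfg,
                                error = conditionMessage(e)),
                           class = "stratified_result")
               })
    } else {
      .fit_cell(.cell_iu_table(ius_by_width[[wkey]], cfg), cfg)
    }
    results[[i]] <- res
  }
  ok <- vapply(results, function(r) is.null(r$error), TRUE)
  summary_df <- do.call(rbind, lapply(results[ok], function(r) {
    data.frame(source = r$config$source_mode,
               criterion = r$config$label_criterion,
               width_s = r$config$width_s, n_ius = r$n_ius,
               n_eating = r$n_eating, n_features = r$n_features,
               chosen_mtry = r$chosen_mtry, stringsAsFactors = FALSE)
  }))
  grid <- structure(list(results = results, summary = summary_df,
                         seed = seed), class = "analysis_grid")
  if (!is.null(out_dir)) export_grid(grid, out_dir)
  grid
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d stratified analyses\n",
              length(x$results)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.analysis_grid <- function(object, ...) object$summary

#' Export a grid run as CSV tables
#'
#' Writes \code{summary.csv} (one row per cell), \code{results.csv} (one
#' row per cell and food: OOB sensitivity, specificity, support) and
#' \code{importance.csv} (one row per cell and variable: raw and 0-100
#' scaled mean Gini decrease) — the tabular backbone of per-food
#' performance and importance figures.
#'
#' @param grid An \code{\link{run_full_grid}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "analysis_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- Filter(function(r) is.null(r$error), grid$results)
  cell_cols <- function(r, df) {
    cbind(data.frame(source = r$config$source_mode,
                     criterion = r$config$label_criterion,
                     width_s = r$config$width_s,
                     stringsAsFactors = FALSE), df)
  }
  results <- do.call(rbind, lapply(ok, function(r) cell_cols(r, r$metrics)))
  importance <- do.call(rbind, lapply(ok, function(r)
    cell_cols(r, r$importances)))
  utils::write.csv(grid$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(results, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(importance, file.path(dir, "importance.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
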