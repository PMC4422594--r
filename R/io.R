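#' Read a multichannel EEG recording
#'
#' CSV recordings have a header `time_s,<CH1>,...` with one row per
#' sample; EDF recordings are standard European Data Format files with
#' channel labels matching the montage. Sampling rate is validated
#' against the timestamps (CSV, 1 ppm regularity) or taken from the
#' header (EDF).
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"` (default: from the file extension).
#' @param montage Optional channel labels to require and order by.
#' @return An [eeg_recording()] tibble.
#' @export
read_recording <- function(path, format = NULL, montage = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") read_recording_csv(path, montage)
  else read_recording_edf(path, montage)
}

read_recording_csv <- function(path, montage = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "time_s") {
    rlang::abort("CSV recordings must start with a `time_s` column")
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1) rlang::abort("recording holds fewer than 2 samples")
  if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    rlang::abort("irregular timestamps (beyond 1 ppm)")
  }
  rate <- 1 / stats::median(dt)
  chans <- setdiff(names(df), "time_s")
  if (!is.null(montage)) {
    missing <- setdiff(montage, chans)
    if (length(missing)) {
      rlang::abort(paste0("missing channel(s): ",
                          paste(missing, collapse = ", ")))
    }
    chans <- montage
  }
  eeg_recording(as.matrix(df[, chans]), rate, chans)
}

#' Write a recording to CSV
#'
#' UTF-8, comma-separated, `.` decimal, header exactly
#' `time_s,<CH1>,...` — round-trips through [read_recording()].
#'
#' @param rec An EEG recording tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  invisible(path)
}

# ---- minimal EDF (16-bit) reader/writer -------------------------------
# Fixed-layout EDF: one data record spanning the whole session; physical
# range taken from the data, digital range -32768..32767.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF file
#'
#' Minimal standard-compliant EDF: 16-bit samples, one data record
#' covering the session. Amplitudes are quantised to the per-channel
#' physical range, so round-trips agree to quantisation tolerance.
#'
#' @param rec An EEG recording tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  x <- rec_matrix(rec)
  rate <- rec_rate(rec)
  mont <- rec_montage(rec)
  ns <- ncol(x)
  n <- nrow(x)
  dur <- n / rate
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(dur, digits = 7), 8), edf_pad(ns, 4),
    paste(edf_pad(mont, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(formatC(pmin_, digits = 6, format = "g"), 8), collapse = ""),
    paste(edf_pad(formatC(pmax_, digits = 6, format = "g"), 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # physical min/max as written (string round-trip) for exact rescaling
  pmin_w <- as.numeric(formatC(pmin_, digits = 6, format = "g"))
  pmax_w <- as.numeric(formatC(pmax_, digits = 6, format = "g"))
  for (j in seq_len(ns)) {
    dig <- round((x[, j] - pmin_w[j]) / (pmax_w[j] - pmin_w[j]) *
                   65535 - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                 # version
  readChar(con, 160, useBytes = TRUE)               # patient + recording
  readChar(con, 16, useBytes = TRUE)                # date + time
  readChar(con, 8, useBytes = TRUE)                 # header bytes
  readChar(con, 44, useBytes = TRUE)                # reserved
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  rd <- function(w) trimws(vapply(seq_len(ns), function(i)
    readChar(con, w, useBytes = TRUE), character(1)))
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  out <- matrix(NA_real_, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[j], size = 2, endian = "little",
                     signed = TRUE)
      phys <- pmin_[j] + (dig - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax_[j] - pmin_[j])
      out[((r - 1) * spr[j] + 1):(r * spr[j]), j] <- phys
    }
  }
  rate <- spr[1] / dur            # dur is seconds per data record
  colnames(out) <- labels
  if (!is.null(montage)) {
    missing <- setdiff(montage, labels)
    if (length(missing)) {
      rlang::abort(paste0("missing channel(s): ",
                          paste(missing, collapse = ", ")))
    }
    out <- out[, montage, drop = FALSE]
    labels <- montage
  }
  eeg_recording(out, rate, labels)
}

# ---- model / result serialization -------------------------------------

#' Serialize a fitted discriminant to JSON
#'
#' Stores the feature list, projection vector, projected class statistics,
#' ridge and variance mode — everything needed for bit-reproducible
#' scoring of new windows.
#'
#' @param model A fitted [flda()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flda_json <- function(model, path) {
  doc <- list(
    features = model$features,
    w = unname(model$w),
    projected = list(mean = model$projected$mean,
                     var = model$projected$var,
                     n = model$projected$n),
    pooled_var = model$pooled_var,
    ridge = model$ridge,
    variance = model$variance,
    priors = c(0.5, 0.5)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a discriminant serialized by [write_flda_json()]
#'
#' @param path JSON path.
#' @return An object of class `flda` usable with [predict.flda()].
#' @export
read_flda_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    w = stats::setNames(doc$w, doc$features),
    features = doc$features,
    projected = tibble::tibble(class = 0:1, mean = doc$projected$mean,
                               var = doc$projected$var, n = doc$projected$n),
    pooled_var = doc$pooled_var, ridge = doc$ridge,
    variance = doc$variance
  ), class = "flda")
}

#' Write a selection result as TSV plus metadata sidecar
#'
#' @param sel An `eeg_selection` object.
#' @param path TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(sel, path) {
  readr::write_tsv(sel$chosen, path, progress = FALSE)
  jsonlite::write_json(
    list(subject_id = sel$subject_id, index_name = sel$index_name,
         folds = sel$folds, seed = sel$seed,
         final_cv_accuracy = sel$final_cv_accuracy,
         plateau_rule = "truncate at last strict improvement",
         tie_break = "higher F, then lower feature index"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- pipeline ---------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. All randomness
#' (fold assignment) derives from the single `seed`.
#'
#' @param data_dir Directory holding session files named
#'   `<subject>_<session>.<ext>` where session is `neutral`, an index
#'   condition, or a clip id.
#' @param out_dir Output directory for all artifacts.
#' @param subjects Character vector of subject ids.
#' @param indices Index conditions to train (default happiness, surprise,
#'   attention).
#' @param clips Clip ids to score.
#' @param format Recording format, `"csv"` or `"edf"`.
#' @param montage,rate,bands,window_s,low,high,transform,folds,seed,peak_threshold
#'   Analysis parameters; see the corresponding stage functions.
#' @param behavior_csv Optional behavioural record CSV (columns
#'   `subject_id`, `clip_id`, `preference_rank`, `stm_rank`,
#'   `recall_rank`, `purchase_intention`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir, subjects,
                            indices = c("happiness", "surprise", "attention"),
                            clips = c("C1", "C2", "C3", "C4"),
                            format = "csv",
                            montage = epoc_montage(), rate = 128,
                            bands = eeg_bands(), window_s = 0.25,
                            low = 0.5, high = 100,
                            transform = "log", folds = 10, seed = 1L,
                            peak_threshold = 0.5, behavior_csv = NULL) {
  stopifnot(rate > 0, window_s > 0, folds > 1, low > 0, high > low)
  structure(as.list(environment()), class = "pipeline_config")
}

session_path <- function(config, subject, session) {
  file.path(config$data_dir,
            paste0(subject, "_", session, ".", config$format))
}

#' Run the full analysis pipeline
#'
#' For every subject: read the neutral and index-condition calibration
#' sessions, preprocess (band-pass, common average reference,
#' quarter-second segmentation), extract band-power features, select
#' features by ANOVA-seeded greedy cross-validation, train the Fisher
#' discriminant on the chosen set, then score every clip session into a
#' normalized index series. Clip summaries, group-average series, peak
#' windows, and (when behavioural records are supplied) behavioural
#' comparisons are written to `out_dir` as TSV, models as JSON, plus a
#' deterministic run log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `selections`, `models`, `series`,
#'   `summary`, `peaks` and (optionally) `behavior`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (d in c("features", "selection", "models", "series", "report")) {
    dir.create(file.path(config$out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  read_sess <- function(subject, session) {
    p <- session_path(config, subject, session)
    if (!file.exists(p)) {
      rlang::abort(sprintf("subject %s: missing %s session file %s",
                           subject, session, p))
    }
    read_recording(p, config$format, config$montage)
  }
  featurize <- function(rec, subject, session) {
    ep <- suppressWarnings(
      eeg_preprocess(rec, config$low, config$high, config$window_s))
    ft <- band_power_features(ep, config$bands, config$transform)
    readr::write_tsv(ft, file.path(config$out_dir, "features",
                                   paste0(subject, "_", session, ".tsv")),
                     progress = FALSE)
    ft
  }

  selections <- list(); models <- list(); all_series <- list()
  for (subject in config$subjects) {
    neutral_ft <- featurize(read_sess(subject, "neutral"), subject, "neutral")
    clip_ft <- lapply(stats::setNames(config$clips, config$clips),
                      function(cl) featurize(read_sess(subject, cl),
                                             subject, cl))
    for (index in config$indices) {
      target_ft <- featurize(read_sess(subject, index), subject, index)
      lab <- label_features(neutral_ft, target_ft)
      sel <- select_features(lab, folds = config$folds, seed = config$seed,
                             subject_id = subject, index_name = index)
      write_selection_tsv(sel, file.path(config$out_dir, "selection",
                                         paste0(subject, "_", index, ".tsv")))
      model <- flda(lab, features = sel$chosen$feature)
      write_flda_json(model, file.path(config$out_dir, "models",
                                       paste0(subject, "_", index, ".json")))
      key <- paste0(subject, ".", index)
      selections[[key]] <- sel
      models[[key]] <- model
      for (cl in config$clips) {
        all_series[[paste0(key, ".", cl)]] <-
          score_clip(clip_ft[[cl]], model, subject, index, cl)
      }
    }
  }
  series <- dplyr::bind_rows(all_series)
  readr::write_tsv(series, file.path(config$out_dir, "series",
                                     "index_series.tsv"), progress = FALSE)
  summary <- summarize_clips(series)
  readr::write_tsv(summary, file.path(config$out_dir, "report",
                                      "clip_summary.tsv"), progress = FALSE)
  peaks <- purrr::map_dfr(config$indices, function(index) {
    purrr::map_dfr(config$clips, function(cl) {
      avg <- group_average_series(
        dplyr::filter(series, .data$index_name == index,
                      .data$clip_id == cl))
      pk <- detect_peaks(avg, config$peak_threshold, config$window_s)
      if (nrow(pk)) dplyr::mutate(pk, index_name = index, clip_id = cl)
      else pk
    })
  })
  readr::write_tsv(peaks, file.path(config$out_dir, "report", "peaks.tsv"),
                   progress = FALSE)
  behavior <- NULL
  if (!is.null(config$behavior_csv)) {
    rec <- readr::read_csv(config$behavior_csv, show_col_types = FALSE,
                           progress = FALSE)
    scored <- score_behavior(rec)
    comps <- purrr::map_dfr(
      intersect(c("preference", "stm", "recall", "purchase_intention"),
                names(scored)),
      function(col) {
        cmp <- compare_groups(scored, value = col)
        dplyr::mutate(tidy(cmp), measure = col,
                      omnibus_p = cmp$omnibus$p_value)
      })
    readr::write_tsv(comps, file.path(config$out_dir, "report",
                                      "behavior_comparisons.tsv"),
                     progress = FALSE)
    behavior <- comps
  }
  log_lines <- c(
    paste0("eegindex version: ",
           as.character(utils::packageVersion("eegindex"))),
    paste0("seed: ", config$seed),
    paste0("folds: ", config$folds),
    paste0("filter: ", config$low, "-", config$high,
           " Hz (upper edge clamped to 0.45 x rate when above Nyquist)"),
    paste0("window_s: ", config$window_s),
    paste0("transform: ", config$transform),
    paste0("peak_threshold: ", config$peak_threshold),
    "posterior: 1-D Gaussian class-conditionals, per-class variance, equal priors",
    "selection plateau rule: truncate at last strict improvement",
    "selection tie-break: higher F, then lower feature index"
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(selections = selections, models = models, series = series,
                 summary = summary, peaks = peaks, behavior = behavior))
}

#' Write a complete synthetic study to disk
#'
#' Generates calibration and clip sessions for several subjects (each with
#' its own seed derived from `seed`), writes them in the pipeline's CSV
#' dialect plus per-clip ground-truth TSVs, and returns the manifest.
#'
#' @param dir Output directory.
#' @param n_subjects Number of subjects.
#' @param effects Planted-effect table (see [synth_config()]).
#' @param clips Named list of clip trajectories (name = clip id); each is
#'   a trajectory accepted by [simulate_commercial()]. The condition whose
#'   effects a clip modulates is given in `clip_conditions`.
#' @param clip_conditions Named character vector mapping clip id to the
#'   condition its trajectory modulates (default: happiness for all).
#' @param session_length,clip_length Durations in seconds.
#' @param seed Master seed.
#' @param ... Further arguments to [synth_config()].
#' @return Tibble manifest of written files, invisibly.
#' @export
simulate_study <- function(dir, n_subjects = 6, effects,
                           clips, clip_conditions = NULL,
                           session_length = 60, clip_length = 30,
                           seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(clip_conditions)) {
    clip_conditions <- stats::setNames(rep("happiness", length(clips)),
                                       names(clips))
  }
  conditions <- unique(c("neutral", effects$condition))
  manifest <- list()
  for (s in seq_len(n_subjects)) {
    subject <- sprintf("S%02d", s)
    sub_seed <- (seed * 1009L + s * 101L) %% .Machine$integer.max
    cfg <- synth_config(effects = effects, session_length = session_length,
                        seed = sub_seed, ...)
    for (cond in conditions) {
      p <- file.path(dir, paste0(subject, "_", cond, ".csv"))
      write_recording_csv(simulate_session(cfg, cond), p)
      manifest[[length(manifest) + 1]] <-
        tibble::tibble(subject_id = subject, session = cond, path = p)
    }
    clip_cfg <- synth_config(effects = effects,
                             session_length = clip_length,
                             seed = sub_seed, ...)
    for (cl in names(clips)) {
      sim <- simulate_commercial(clip_cfg, clips[[cl]], clip_id = cl,
                                 condition = clip_conditions[[cl]])
      p <- file.path(dir, paste0(subject, "_", cl, ".csv"))
      write_recording_csv(sim$recording, p)
      readr::write_tsv(sim$truth,
                       file.path(dir, paste0(subject, "_", cl, "_truth.tsv")),
                       progress = FALSE)
      manifest[[length(manifest) + 1]] <-
        tibble::tibble(subject_id = subject, session = cl, path = p)
    }
  }
  invisible(dplyr::bind_rows(manifest))
}
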