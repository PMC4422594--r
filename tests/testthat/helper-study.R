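# One seed of the end-to-end recovery study: 6 subjects, 4 clips, the
# happiness-assigned cells (FC5 gamma, T8 high beta) planted at
# multiplier 2.5 in clip C1 under a trapezoid trajectory; the other three
# clips carry no effect. Returns whether C1 ranked first on the happiness
# index and the correlation of the group-average series with the planted
# trajectory.
happiness_effects <- function(multiplier = 2.5) {
  tibble::tibble(condition = rep("happiness", 2),
                 channel = c("FC5", "T8"),
                 band = c("gamma", "high_beta"),
                 multiplier = multiplier)
}

planted_trajectory <- function() {
  tibble::tibble(time_s = c(0, 7.5, 22.5, 30), intensity = c(0, 1, 1, 0))
}

run_recovery_seed <- function(s, n_subjects = 6, multiplier = 2.5) {
  eff <- happiness_effects(multiplier)
  traj <- planted_trajectory()
  series <- list()
  truth <- NULL
  for (subj in seq_len(n_subjects)) {
    sub_seed <- (s * 1009L + subj * 101L) %% .Machine$integer.max
    cfg <- synth_config(effects = eff, session_length = 60, seed = sub_seed)
    ccfg <- synth_config(effects = eff, session_length = 30, seed = sub_seed)
    neu <- suppressWarnings(
      band_power_features(eeg_preprocess(simulate_session(cfg, "neutral"))))
    hap <- suppressWarnings(
      band_power_features(eeg_preprocess(simulate_session(cfg, "happiness"))))
    lab <- label_features(neu, hap)
    sel <- select_features(lab, seed = s)
    fit <- flda(lab, features = sel$chosen$feature)
    for (cl in paste0("C", 1:4)) {
      sim <- simulate_commercial(
        ccfg, if (cl == "C1") traj else trajectory_constant(0), cl)
      ft <- suppressWarnings(
        band_power_features(eeg_preprocess(sim$recording)))
      series[[paste(subj, cl)]] <-
        score_clip(ft, fit, paste0("S", subj), "happiness", cl)
      if (cl == "C1" && is.null(truth)) truth <- sim$truth
    }
  }
  all_series <- dplyr::bind_rows(series)
  sm <- summarize_clips(all_series)
  avg <- group_average_series(
    dplyr::filter(all_series, .data$clip_id == "C1"))
  list(top_is_planted = sm$clip_id[sm$rank == 1] == "C1",
       trajectory_cor = stats::cor(avg$value, truth$intensity))
}
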