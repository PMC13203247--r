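#' Per-trial metrics for a set of simulated trials
#'
#' @param trials List of [simulate_trial()] results.
#' @param window An [epoch_window()].
#' @param ... Passed to [compute_trial_metrics()].
#' @return Data frame, one row per trial.
#' @keywords internal
trials_metrics_table <- function(trials, window = vision_off_window(), ...) {
  rows <- lapply(seq_along(trials), function(i) {
    m <- compute_trial_metrics(as_force_recording(trials[[i]]),
                               window = window, ...)
    cbind(data.frame(trial = i, seed = trials[[i]]$realization$seed),
          as.data.frame(m))
  })
  do.call(rbind, rows)
}

metric_columns <- function() {
  c("undershoot", "rmse", "band_power_1_3",
    names(coherence_bands()))
}

summarize_metric_rows <- function(tab) {
  cols <- intersect(metric_columns(), names(tab))
  out <- data.frame(n_trials = nrow(tab))
  for (cl in cols) {
    out[[paste0(cl, "_mean")]] <- mean(tab[[cl]])
    # sample SD (n - 1); a single trial yields NA, flagged rather than 0
    out[[paste0(cl, "_sd")]] <- if (nrow(tab) > 1) stats::sd(tab[[cl]]) else NA_real_
  }
  out
}

#' Dose-response sweep over the proprioceptive gain
#'
#' Simulates `n_trials` replicate trials at each gain value and summarizes
#' the non-visual-window outcomes (mean and sample SD across trials). Trial
#' seed streams are keyed by `(master_seed, g value, trial index)` via
#' [trial_seed()], so results are invariant to grid ordering and to adding
#' grid points. The default grid spans the nominal gain range 0.20--0.80
#' and includes the two condition values 0.25 and 0.70.
#'
#' @param g_values Proprioceptive gain grid (each > 0).
#' @param n_trials Replicate trials per grid point.
#' @param params Baseline [model_params()] (its `g_proprio` is overridden).
#' @param master_seed Non-negative integer master seed.
#' @param window Analysis window; default `[23, 40)` s.
#' @return An object of class `"dose_response_result"`: a data frame with
#'   one row per gain value (`g_proprio`, `n_trials`, `<metric>_mean`,
#'   `<metric>_sd`), with the master seed and per-trial table in
#'   attributes.
#' @examples
#' \donttest{
#' dr <- dose_response_sweep(c(0.25, 0.70), n_trials = 5, master_seed = 1)
#' dr[, c("g_proprio", "undershoot_mean", "band_power_1_3_mean")]
#' }
#' @export
dose_response_sweep <- function(g_values = c(0.20, 0.25, 0.30, 0.40, 0.50,
                                             0.60, 0.70, 0.80),
                                n_trials = 20,
                                params = model_params(),
                                master_seed = 1,
                                window = vision_off_window()) {
  stopifnot(length(g_values) >= 1, all(g_values > 0))
  per_g <- lapply(g_values, function(g) {
    pg <- params
    pg$g_proprio <- g
    validate_model_params(pg)
    trials <- simulate_condition(pg, n_trials = n_trials,
                                 master_seed = master_seed)
    tab <- trials_metrics_table(trials, window = window)
    cbind(data.frame(g_proprio = g), summarize_metric_rows(tab),
          row.names = NULL)
  })
  out <- do.call(rbind, per_g)
  attr(out, "master_seed") <- master_seed
  attr(out, "window") <- window
  class(out) <- c("dose_response_result", "data.frame")
  out
}

#' Sham versus stimulation condition comparison
#'
#' Simulates the two modeled conditions -- sham (`g_proprio = 0.25`) and
#' anodal stimulation (`g_proprio = 0.70`) -- with independent seed streams
#' and summarizes the non-visual-window outcomes per condition, plus the
#' stimulation-minus-sham differences of the metric means.
#'
#' @param g_sham,g_tdcs Proprioceptive gains of the two conditions.
#' @param n_trials Replicate trials per condition.
#' @param params Baseline [model_params()].
#' @param master_seed Master seed (streams are keyed by each condition's
#'   gain value).
#' @param window Analysis window.
#' @return An object of class `"condition_comparison"`: a list with
#'   `summary` (two-row data frame), `difference` (named vector of mean
#'   differences, tdcs - sham), and the per-trial tables.
#' @export
condition_comparison <- function(g_sham = 0.25, g_tdcs = 0.70,
                                 n_trials = 20,
                                 params = model_params(),
                                 master_seed = 1,
                                 window = vision_off_window()) {
  one <- function(g, label) {
    pg <- params
    pg$g_proprio <- g
    validate_model_params(pg)
    trials <- simulate_condition(pg, n_trials = n_trials,
                                 master_seed = master_seed)
    tab <- trials_metrics_table(trials, window = window)
    list(summary = cbind(data.frame(condition = label, g_proprio = g),
                         summarize_metric_rows(tab), row.names = NULL),
         table = tab)
  }
  sham <- one(g_sham, "sham")
  tdcs <- one(g_tdcs, "tdcs")
  summary <- rbind(sham$summary, tdcs$summary)
  mcols <- paste0(metric_columns(), "_mean")
  diff <- unlist(summary[2, mcols]) - unlist(summary[1, mcols])
  names(diff) <- metric_columns()
  structure(list(summary = summary, difference = diff,
                 trials_sham = sham$table, trials_tdcs = tdcs$table,
                 master_seed = master_seed),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (non-visual window)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s (g=%.2f, n=%d): undershoot %.2f +/- %.2f %%, RMSE %.2f N, 1-3 Hz power %.4g N^2\n",
                s$condition[i], s$g_proprio[i], s$n_trials[i],
                s$undershoot_mean[i], s$undershoot_sd[i],
                s$rmse_mean[i], s$band_power_1_3_mean[i]))
  cat(sprintf("  difference (tdcs - sham): undershoot %.2f pp, 1-3 Hz power x%.2f\n",
              x$difference[["undershoot"]],
              s$band_power_1_3_mean[2] / s$band_power_1_3_mean[1]))
  invisible(x)
}

#' Visual versus non-visual epoch contrast
#'
#' Computes the outcome set on both standard windows for each trial and
#' reports per-epoch summaries together with the ratio of mean RMSE
#' (non-visual over visual). Because the non-visual RMSE contains the
#' drift-induced bias while the visual epoch is unbiased, this ratio is
#' dominated by the undershoot; the fluctuation ratio (SD of force about
#' its window mean) isolates the variability increase.
#'
#' @param trials List of [simulate_trial()] results sharing one parameter
#'   set.
#' @param ... Passed to [compute_trial_metrics()].
#' @return An object of class `"vision_contrast"`: list with `table` (one
#'   row per trial x window, including `force_sd`, the SD of the summed
#'   force about its window mean), `rmse_ratio` (OFF/ON mean RMSE) and
#'   `sd_ratio` (OFF/ON mean fluctuation SD).
#' @export
vision_on_off_contrast <- function(trials, ...) {
  stopifnot(length(trials) >= 1)
  p <- trials[[1]]$params
  wins <- list(vision_on_window(p), vision_off_window(p))
  rows <- list()
  for (tr in trials) {
    rec <- lowpass_filter(as_force_recording(tr))
    for (w in wins) {
      m <- compute_trial_metrics(rec, window = w, lowpass = FALSE, ...)
      idx <- window_indices(w, rec$sampling_rate, length(rec$force_left))
      fsum <- rec$force_left[idx] + rec$force_right[idx]
      row <- cbind(data.frame(seed = tr$realization$seed),
                   as.data.frame(m))
      row$force_sd <- stats::sd(fsum)
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  mean_on <- function(col) mean(tab[[col]][tab$window == "vision_on"])
  mean_off <- function(col) mean(tab[[col]][tab$window == "vision_off"])
  structure(list(
    table = tab,
    rmse_ratio = mean_off("rmse") / mean_on("rmse"),
    sd_ratio = mean_off("force_sd") / mean_on("force_sd")
  ), class = "vision_contrast")
}

#' @export
print.vision_contrast <- function(x, ...) {
  on <- x$table[x$table$window == "vision_on", ]
  off <- x$table[x$table$window == "vision_off", ]
  cat("Visual vs non-visual epoch contrast\n")
  cat(sprintf("  visual:     RMSE %.3f N, fluctuation SD %.3f N\n",
              mean(on$rmse), mean(on$force_sd)))
  cat(sprintf("  non-visual: RMSE %.3f N, fluctuation SD %.3f N\n",
              mean(off$rmse), mean(off$force_sd)))
  cat(sprintf("  ratios (off/on): RMSE %.2f, fluctuation SD %.2f\n",
              x$rmse_ratio, x$sd_ratio))
  invisible(x)
}

#' Simulate a two-group pre/post study table
#'
#' Generates the study layout used by the statistical battery: `n_per_group`
#' participants per group, one simulated trial per epoch (PRE, POST), with
#' each group's trials drawn under its own parameter set. Under the null
#' (identical parameter sets) every PRE/POST difference is pure
#' between-trial variability.
#'
#' @param params_sham,params_tdcs [model_params()] for the two groups.
#' @param n_per_group Participants per group.
#' @param master_seed Master seed; participant x epoch trials get distinct
#'   seeds derived from it.
#' @param window Analysis window for the metrics.
#' @return A long-format study table (see [build_report()]): data frame
#'   with columns `id`, `group`, `metric`, `pre`, `post`.
#' @export
simulate_study_table <- function(params_sham = model_params(g_proprio = 0.25),
                                 params_tdcs = model_params(g_proprio = 0.25),
                                 n_per_group = 12,
                                 master_seed = 1,
                                 window = vision_off_window()) {
  groups <- list(sham = params_sham, tdcs = params_tdcs)
  rows <- list()
  id <- 0L
  for (gname in names(groups)) {
    pg <- groups[[gname]]
    for (i in seq_len(n_per_group)) {
      id <- id + 1L
      seeds <- c(pre = trial_seed(master_seed, pg$g_proprio, 2L * id - 1L),
                 post = trial_seed(master_seed, pg$g_proprio, 2L * id))
      met <- lapply(seeds, function(s) {
        compute_trial_metrics(as_force_recording(simulate_trial(pg, s)),
                              window = window)
      })
      flat <- lapply(met, function(m) {
        c(undershoot = m$undershoot, rmse = m$rmse,
          band_power_1_3 = m$band_power_1_3, m$coherence_bands)
      })
      rows[[id]] <- data.frame(
        id = sprintf("P%02d", id), group = gname,
        metric = names(flat$pre),
        pre = unname(flat$pre), post = unname(flat$post),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
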