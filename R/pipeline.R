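#' Configuration of a full classification experiment
#'
#' @param experiment `"TFAAT"` (screened region x band averages, F24) or
#'   `"PBTST"` (fixed prefrontal beta 9-window time series).
#' @param conditions Conditions to analyse; umbrella conditions `MSIT` and
#'   `STMT` are the unions of their low/high-demand trials.
#' @param mt_config A [multitaper_config()].
#' @param alpha Screening threshold on BH q-values.
#' @param classifiers Classifier set for [run_validation()].
#' @param n_iterations,seed_start,n_test_neutral,n_test_risky LPSO
#'   parameters, see [make_lpso_plan()].
#' @param screen_within_fold If `TRUE`, TFAAT feature screening is re-run
#'   inside every LPSO training fold (no selection leakage); the default
#'   `FALSE` screens once on the full dataset before validation, matching
#'   the original analysis design.
#' @return An `ExperimentConfig` list.
#' @export
experiment_config <- function(experiment = c("TFAAT", "PBTST"),
                              conditions = c("ML", "MH", "SL", "SH",
                                             "MSIT", "STMT", "Rest"),
                              mt_config = multitaper_config(),
                              alpha = 1e-3,
                              classifiers = c("lr", "rf", "svm", "gb"),
                              n_iterations = 100, seed_start = 42,
                              n_test_neutral = 5, n_test_risky = 4,
                              screen_within_fold = FALSE) {
  experiment <- match.arg(experiment)
  structure(
    list(experiment = experiment, conditions = conditions,
         mt_config = mt_config, alpha = alpha, classifiers = classifiers,
         n_iterations = n_iterations, seed_start = seed_start,
         n_test_neutral = n_test_neutral, n_test_risky = n_test_risky,
         screen_within_fold = screen_within_fold),
    class = "ExperimentConfig"
  )
}

#' Run a classification experiment over task conditions
#'
#' For each requested condition: trials are selected (umbrella conditions
#' pool their subclasses), reduced to the F216 feature space, screened in
#' both F216 and F24, and validated under the LPSO plan with the requested
#' classifiers. TFAAT classifies the screened F24 features (a condition
#' whose screening selects nothing is skipped with a message); PBTST
#' classifies the fixed 9-feature prefrontal beta set without screening.
#'
#' @param epochs An [epoch_set()] containing all requested conditions.
#' @param config An [experiment_config()].
#' @return A report bundle: per-condition `MetricsReport`s, the radar-chart
#'   summary table (5 metrics x classifier x condition with stars), the
#'   percentage confusion matrices and the F24/F216 region-concentration
#'   ratio tables.
#' @export
run_experiment <- function(epochs, config = experiment_config()) {
  stopifnot(inherits(epochs, "EpochSet"),
            inherits(config, "ExperimentConfig"))
  reports <- list()
  screens_f24 <- list()
  screens_f216 <- list()
  for (cond in config$conditions) {
    sub <- subset_trials(epochs, conditions = cond)
    if (n_trials(sub) == 0) stop("condition not present: ", cond)
    f216 <- f216_from_epochs(sub, config$mt_config)
    f24 <- reduce_to_f24(f216)
    screens_f216[[cond]] <- screen_features(f216, alpha = config$alpha)
    screens_f24[[cond]] <- screen_features(f24, alpha = config$alpha)
    if (config$experiment == "TFAAT") {
      if (config$screen_within_fold) {
        fm <- f24
        alpha <- config$alpha
        regions <- f24$feature_regions
        selector <- function(x_tr, y_tr) {
          which(welch_bh_q(x_tr, y_tr) < alpha)
        }
      } else {
        sel <- screens_f24[[cond]]$selected
        if (!any(sel)) {
          message("run_experiment: no feature survives screening for ",
                  cond, "; condition skipped")
          next
        }
        fm <- feature_matrix(f24$values[, sel, drop = FALSE],
                             f24$feature_names[sel], "F24",
                             f24$trials_meta, f24$feature_regions[sel])
        selector <- NULL
      }
    } else {
      fm <- select_pbtst(f216)
      selector <- NULL
    }
    plan <- make_lpso_plan(subject_groups(sub),
                           n_iterations = config$n_iterations,
                           seed_start = config$seed_start,
                           n_test_neutral = config$n_test_neutral,
                           n_test_risky = config$n_test_risky)
    reports[[cond]] <- run_validation(fm, plan,
                                      classifiers = config$classifiers,
                                      per_fold_select = selector)
  }
  radar <- do.call(rbind, lapply(names(reports), function(cond) {
    cbind(condition = cond, reports[[cond]]$summary)
  }))
  structure(
    list(experiment = config$experiment, reports = reports, radar = radar,
         confusion_pct = lapply(reports, `[[`, "confusion_pct"),
         ratio_f24 = ratio_report(screens_f24),
         ratio_f216 = ratio_report(screens_f216),
         screens_f24 = screens_f24, screens_f216 = screens_f216),
    class = "ExperimentReport"
  )
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport:", x$experiment, "over",
      length(x$reports), "condition(s)\n")
  if (!is.null(x$radar)) {
    auc <- x$radar[x$radar$metric == "auc", ]
    print(auc[, c("condition", "classifier", "mean", "stars")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Group-mean prefrontal beta PSD time courses
#'
#' For each requested condition and subject group, the mean of the
#' `Pre_beta_1..9` features over trials: the 9-point prefrontal beta power
#' time series whose group gap the classification experiments exploit.
#'
#' @param f216 A `FeatureMatrix` with `space_tag = "F216"` covering the
#'   requested conditions.
#' @param conditions Conditions to tabulate (default the memory task and
#'   its subclasses); umbrella names pool their subclasses.
#' @param mt_config,t0_offset_ms Windowing parameters used to recover the
#'   window center times.
#' @param fs Sampling rate, Hz.
#' @return Data frame: `condition`, `group`, `window`, `time_s`, `psd`.
#' @export
psd_timeseries <- function(f216, conditions = c("SL", "SH", "STMT"),
                           mt_config = multitaper_config(), fs = 250,
                           t0_offset_ms = -80) {
  stopifnot(inherits(f216, "FeatureMatrix"), f216$space_tag == "F216")
  pb <- select_pbtst(f216)
  n_win <- ncol(pb$values)
  times <- window_center_times(n_win, mt_config$nperseg, mt_config$noverlap,
                               fs, t0_offset_ms)
  rows <- list()
  for (cond in conditions) {
    expanded <- switch(cond, MSIT = c("MSIT", "ML", "MH"),
                       STMT = c("STMT", "SL", "SH"), cond)
    in_cond <- pb$trials_meta$condition %in% expanded
    for (grp in c("neutral", "risky")) {
      sel <- in_cond & pb$trials_meta$group == grp
      if (!any(sel)) stop("empty group ", grp, " for condition ", cond)
      m <- colMeans(pb$values[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, group = grp, window = seq_len(n_win),
        time_s = times, psd = unname(m), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
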