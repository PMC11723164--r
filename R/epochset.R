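#' Construct an epoched EEG container
#'
#' The universal exchange container of the pipeline: a trials x channels x
#' samples array in microvolts plus per-trial metadata and the montage.
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param t0_offset_ms Position of stimulus onset within the epoch, in ms
#'   (negative = pre-stimulus baseline; default -80).
#' @param channel_names Character vector of channel labels (length = dim 2).
#' @param montage A [channel_montage()] covering all channels.
#' @param trials_meta Data frame with one row per trial; columns
#'   `subject_id`, `group` (`"neutral"`/`"risky"`), `condition`, and
#'   optionally `response_time` (ms) and `correct` (logical).
#' @return An `EpochSet` object.
#' @export
epoch_set <- function(data, fs, t0_offset_ms = -80, channel_names, montage,
                      trials_meta) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  stopifnot(fs > 0)
  if (length(channel_names) != dim(data)[2]) {
    stop("channel_names length must equal the channel dimension")
  }
  if (!identical(sort(channel_names), sort(montage$channel_names))) {
    stop("montage channels do not match channel_names")
  }
  stopifnot(is.data.frame(trials_meta))
  if (nrow(trials_meta) != dim(data)[1]) {
    stop("trials_meta must have one row per trial")
  }
  req <- c("subject_id", "group", "condition")
  if (!all(req %in% names(trials_meta))) {
    stop("trials_meta needs columns: ", paste(req, collapse = ", "))
  }
  grp_tab <- unique(trials_meta[, c("subject_id", "group")])
  if (anyDuplicated(grp_tab$subject_id)) {
    stop("a subject carries more than one group label")
  }
  structure(
    list(data = data, fs = fs, t0_offset_ms = t0_offset_ms,
         channel_names = channel_names, montage = montage,
         trials_meta = trials_meta),
    class = "EpochSet"
  )
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  epoch onset offset: %g ms\n", x$t0_offset_ms))
  cat("  subjects:", length(unique(x$trials_meta$subject_id)),
      " groups:", paste(names(table(x$trials_meta$group)), collapse = "/"),
      "\n")
  cat("  conditions:",
      paste(sprintf("%s(%d)", names(table(x$trials_meta$condition)),
                    table(x$trials_meta$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in an EpochSet
#' @param epochs An `EpochSet`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an EpochSet by trial index or condition
#'
#' @param epochs An `EpochSet`.
#' @param trials Integer or logical trial index.
#' @param conditions Optional character vector; keeps trials whose condition
#'   is in the set. The umbrella conditions `MSIT` and `STMT` expand to
#'   `ML`+`MH` and `SL`+`SH` respectively (trials labelled with the umbrella
#'   name directly are also kept).
#' @return An `EpochSet` with the selected trials, order preserved.
#' @export
subset_trials <- function(epochs, trials = NULL, conditions = NULL) {
  keep <- rep(TRUE, n_trials(epochs))
  if (!is.null(conditions)) {
    expanded <- unlist(lapply(conditions, function(cc) {
      switch(cc, MSIT = c("MSIT", "ML", "MH"), STMT = c("STMT", "SL", "SH"),
             cc)
    }))
    keep <- keep & epochs$trials_meta$condition %in% expanded
  }
  if (!is.null(trials)) {
    sel <- rep(FALSE, n_trials(epochs))
    sel[trials] <- TRUE
    keep <- keep & sel
  }
  idx <- which(keep)
  epoch_set(
    data = epochs$data[idx, , , drop = FALSE],
    fs = epochs$fs, t0_offset_ms = epochs$t0_offset_ms,
    channel_names = epochs$channel_names, montage = epochs$montage,
    trials_meta = epochs$trials_meta[idx, , drop = FALSE]
  )
}

#' Per-subject group labels of an EpochSet
#' @param epochs An `EpochSet`.
#' @return Named character vector, subject id -> group.
#' @export
subject_groups <- function(epochs) {
  tab <- unique(epochs$trials_meta[, c("subject_id", "group")])
  stats::setNames(as.character(tab$group), as.character(tab$subject_id))
}
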