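#' Build a Leave-p%-Subjects-Out split plan
#'
#' For each iteration `i` the seed `seed_start + i - 1` is set and a fixed
#' test composition (default 5 neutral + 4 risky subjects) is sampled
#' without replacement; all remaining subjects train. With the study's
#' 21 + 18 subjects and the default composition, p is about 23%, inside
#' the 20-25% design range. Test sets may overlap across iterations;
#' train and test are subject-disjoint within every iteration.
#'
#' @param groups Named character vector, subject id -> `"neutral"`/`"risky"`
#'   (see [subject_groups()]).
#' @param n_iterations Number of iterations (default 100).
#' @param seed_start First iteration seed (default 42; iteration `i` uses
#'   `seed_start + i - 1`, so the default covers seeds 42..141).
#' @param n_test_neutral,n_test_risky Test-set composition.
#' @return A `SplitPlan`.
#' @export
make_lpso_plan <- function(groups, n_iterations = 100, seed_start = 42,
                           n_test_neutral = 5, n_test_risky = 4) {
  neutral <- names(groups)[groups == "neutral"]
  risky <- names(groups)[groups == "risky"]
  if (length(neutral) < n_test_neutral + 1 ||
      length(risky) < n_test_risky + 1) {
    stop("too few subjects: need at least one train subject per group ",
         "beyond the test composition")
  }
  seeds <- seq.int(seed_start, length.out = n_iterations)
  iterations <- lapply(seq_len(n_iterations), function(i) {
    set.seed(seeds[i])
    test <- c(sample(neutral, n_test_neutral), sample(risky, n_test_risky))
    list(seed = seeds[i], test_subjects = test,
         train_subjects = setdiff(names(groups), test))
  })
  structure(
    list(iterations = iterations, seeds = seeds, groups = groups,
         n_test_neutral = n_test_neutral, n_test_risky = n_test_risky,
         p_percent = (n_test_neutral + n_test_risky) / length(groups) * 100),
    class = "SplitPlan"
  )
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat(sprintf(
    "SplitPlan: %d iterations, test %d neutral + %d risky (p = %.1f%%)\n",
    length(x$iterations), x$n_test_neutral, x$n_test_risky, x$p_percent))
  invisible(x)
}

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve by the trapezoidal rule over the score-sorted
#' operating points (ties grouped), equivalent to the Mann-Whitney
#' pair-counting estimator with half-weight ties.
#'
#' @param is_positive Logical vector: true class is the positive class.
#' @param scores Numeric classifier scores, higher = more positive.
#' @return AUC in `[0, 1]`; 0 with a message if a class is empty.
#' @export
roc_auc_trapezoid <- function(is_positive, scores) {
  stopifnot(length(is_positive) == length(scores))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    message("roc_auc_trapezoid: degenerate class counts, AUC set to 0")
    return(0)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- is_positive[ord]
  last <- cumsum(rle(s)$lengths)  # indices closing each tie group
  tpr <- c(0, cumsum(y)[last] / n_pos, 1)
  fpr <- c(0, cumsum(!y)[last] / n_neg, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Binary confusion matrix in true-class rows
#'
#' Rows are the true classes (positive first), columns the predictions:
#' `rbind(c(TP, FN), c(FP, TN))`.
#'
#' @param tp,fp,fn,tn Trial counts.
#' @return 2x2 matrix with dimnames `true`/`predicted`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
         dimnames = list(true = c("risky", "neutral"),
                         predicted = c("risky", "neutral")))
}

#' Class-weighted binary classification metrics
#'
#' Accuracy plus precision, recall, F1 and ROC AUC weighted over both
#' classes, each treated in turn as the positive class, with weights
#' `w_c = N_c / sum(N_c)` from the true class counts of the scored set.
#' Degenerate denominators contribute 0 to the weighted sums.
#'
#' @param labels Character/factor true labels (`"neutral"`/`"risky"`).
#' @param predicted Predicted labels, same coding.
#' @param scores Numeric scores, higher = more `"risky"`.
#' @param positive Positive class for the confusion counts (default risky).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`
#'   (all weighted except accuracy) and the counts `tp`, `fp`, `fn`, `tn`.
#' @export
weighted_metrics <- function(labels, predicted, scores,
                             positive = "risky") {
  labels <- as.character(labels)
  predicted <- as.character(predicted)
  if (length(labels) == 0) stop("empty input")
  classes <- c(positive, setdiff(c("neutral", "risky"), positive))
  n <- length(labels)
  w <- vapply(classes, function(cc) sum(labels == cc), numeric(1)) / n
  per_class <- lapply(classes, function(cc) {
    tp <- sum(predicted == cc & labels == cc)
    fp <- sum(predicted == cc & labels != cc)
    fn <- sum(predicted != cc & labels == cc)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    sc <- if (cc == positive) scores else -scores
    list(precision = prec, recall = rec, f1 = f1,
         auc = roc_auc_trapezoid(labels == cc, sc))
  })
  wsum <- function(field) {
    sum(w * vapply(per_class, `[[`, numeric(1), field))
  }
  tp <- sum(predicted == positive & labels == positive)
  fp <- sum(predicted == positive & labels != positive)
  fn <- sum(predicted != positive & labels == positive)
  tn <- sum(predicted != positive & labels != positive)
  list(accuracy = (tp + tn) / n,
       precision = wsum("precision"), recall = wsum("recall"),
       f1 = wsum("f1"), auc = wsum("auc"),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Aggregate per-iteration confusion matrices to percentages
#'
#' Each iteration's matrix is row-normalized by true class to percentages
#' (rows sum to 100), then averaged across iterations.
#'
#' @param confusions List of 2x2 [confusion_matrix()] objects.
#' @return 2x2 percentage matrix.
#' @export
aggregate_confusion <- function(confusions) {
  stopifnot(length(confusions) >= 1)
  mats <- lapply(confusions, function(m) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m / rs * 100
  })
  Reduce(`+`, mats) / length(mats)
}

#' One-tailed test of a metric series against chance
#'
#' One-sample one-tailed t-test of mean > `chance` over the per-iteration
#' metric values. A zero-variance series is conservatively assigned p = 1.
#'
#' @param metric_series Numeric vector (at least 2 values).
#' @param chance Chance level (default 0.5).
#' @return List with `p_value` and `stars` (see [significance_stars()]).
#' @export
significance_vs_chance <- function(metric_series, chance = 0.5) {
  if (length(metric_series) < 2) stop("need at least 2 values")
  if (stats::sd(metric_series) == 0) {
    message("significance_vs_chance: zero-variance series, p set to 1")
    p <- 1
  } else {
    p <- stats::t.test(metric_series, mu = chance,
                       alternative = "greater")$p.value
  }
  list(p_value = p, stars = significance_stars(p))
}

#' Star coding of p-values
#'
#' `***` for p < 1e-3, `**` for p < 1e-2, `*` for p < 5e-2, otherwise "".
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-3) "***" else if (pp < 1e-2) "**" else
      if (pp < 5e-2) "*" else ""
  }, character(1))
}

# ---- classifier backends ------------------------------------------------

# Each backend fits on standardized train features and returns
# list(predicted = labels, scores = higher-is-risky).
fit_predict <- function(method, x_train, y_train, x_test, seed) {
  yf <- factor(y_train, levels = c("neutral", "risky"))
  switch(
    method,
    lr = {
      fit <- suppressWarnings(stats::glm.fit(
        cbind(1, x_train), as.integer(yf) - 1L,
        family = stats::binomial()))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      sc <- drop(stats::plogis(cbind(1, x_test) %*% beta))
      list(predicted = ifelse(sc > 0.5, "risky", "neutral"), scores = sc)
    },
    rf = {
      fit <- ranger::ranger(x = x_train, y = yf, probability = TRUE,
                            num.threads = 1, seed = seed)
      sc <- stats::predict(fit, data = x_test,
                           num.threads = 1)$predictions[, "risky"]
      list(predicted = ifelse(sc > 0.5, "risky", "neutral"), scores = sc)
    },
    svm = {
      fit <- e1071::svm(x = x_train, y = yf, kernel = "radial",
                        scale = FALSE)
      pred <- stats::predict(fit, x_test, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # decision values are signed towards the class named first in the
      # "a/b" column label
      if (!startsWith(colnames(attr(pred, "decision.values"))[1], "risky")) {
        dv <- -dv
      }
      list(predicted = as.character(pred), scores = dv)
    },
    gb = {
      set.seed(seed)
      fit <- xgboost::xgboost(x = x_train, y = yf, nrounds = 100,
                              nthreads = 1, verbosity = 0)
      sc <- stats::predict(fit, x_test, type = "response")
      if (is.matrix(sc)) sc <- sc[, "risky"]
      list(predicted = ifelse(sc > 0.5, "risky", "neutral"), scores = sc)
    },
    stop("unknown classifier: ", method)
  )
}

#' Cross-subject validation of classifiers on a feature matrix
#'
#' Runs every iteration of a [make_lpso_plan()]: trials of the train
#' subjects fit each classifier, trials of the test subjects are scored.
#' Features are standardized per fold with train-fold statistics only.
#' Per iteration and classifier the class-weighted metrics and the
#' confusion matrix are recorded; the report aggregates means, percentage
#' confusion matrices and one-tailed significance vs chance per metric.
#'
#' @param fm A `FeatureMatrix`.
#' @param plan A `SplitPlan` over the subjects present in `fm`.
#' @param classifiers Subset of `c("lr", "rf", "svm", "gb")` (logistic
#'   regression, random forest, RBF-kernel SVM, gradient boosting).
#' @param per_fold_select Optional function `(x_train, y_train) ->
#'   column indices`, applied per iteration to re-select features on the
#'   train fold only (nested screening); default uses all columns.
#' @return A `MetricsReport`: `per_iteration` data frame, `summary` data
#'   frame (mean metric, p-value and stars per classifier x metric) and
#'   `confusion_pct` (percentage matrix per classifier).
#' @export
run_validation <- function(fm, plan,
                           classifiers = c("lr", "rf", "svm", "gb"),
                           per_fold_select = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"), inherits(plan, "SplitPlan"))
  classifiers <- match.arg(classifiers, c("lr", "rf", "svm", "gb"),
                           several.ok = TRUE)
  sid <- as.character(fm$trials_meta$subject_id)
  labels <- as.character(fm$trials_meta$group)
  missing <- setdiff(names(plan$groups), unique(sid))
  if (length(missing)) {
    stop("plan subjects absent from the feature matrix: ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  confusions <- stats::setNames(
    lapply(classifiers, function(m) list()), classifiers)
  for (it in plan$iterations) {
    if (length(intersect(it$train_subjects, it$test_subjects)) > 0) {
      stop("subject leakage in split plan")  # unreachable by construction
    }
    tr <- sid %in% it$train_subjects
    te <- sid %in% it$test_subjects
    x_tr <- fm$values[tr, , drop = FALSE]
    x_te <- fm$values[te, , drop = FALSE]
    if (!is.null(per_fold_select)) {
      keep <- per_fold_select(x_tr, labels[tr])
      if (length(keep) == 0) next
      x_tr <- x_tr[, keep, drop = FALSE]
      x_te <- x_te[, keep, drop = FALSE]
    }
    mu <- colMeans(x_tr)
    sdev <- apply(x_tr, 2, stats::sd)
    sdev[sdev == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sdev, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sdev, "/")
    for (m in classifiers) {
      res <- fit_predict(m, x_tr, labels[tr], x_te, it$seed)
      met <- weighted_metrics(labels[te], res$predicted, res$scores)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration_seed = it$seed, classifier = m,
        accuracy = met$accuracy, precision = met$precision,
        recall = met$recall, f1 = met$f1, auc = met$auc,
        tp = met$tp, fp = met$fp, fn = met$fn, tn = met$tn,
        stringsAsFactors = FALSE
      )
      confusions[[m]][[length(confusions[[m]]) + 1L]] <-
        confusion_matrix(met$tp, met$fp, met$fn, met$tn)
    }
  }
  per_iteration <- do.call(rbind, rows)
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- do.call(rbind, lapply(classifiers, function(m) {
    sub <- per_iteration[per_iteration$classifier == m, , drop = FALSE]
    do.call(rbind, lapply(metric_names, function(mn) {
      sig <- significance_vs_chance(sub[[mn]])
      data.frame(classifier = m, metric = mn, mean = mean(sub[[mn]]),
                 p_value = sig$p_value, stars = sig$stars,
                 stringsAsFactors = FALSE)
    }))
  }))
  confusion_pct <- lapply(confusions, aggregate_confusion)
  structure(
    list(per_iteration = per_iteration, summary = summary,
         confusion_pct = confusion_pct, classifiers = classifiers),
    class = "MetricsReport"
  )
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport over", length(unique(x$per_iteration$iteration_seed)),
      "iterations\n")
  auc <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-4s mean AUC %.3f %s\n", auc$classifier[i],
                auc$mean[i], auc$stars[i]))
  }
  invisible(x)
}
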