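study_groups <- function() {
  setNames(c(rep("neutral", 21), rep("risky", 18)),
           c(sprintf("N%02d", 1:21), sprintf("R%02d", 1:18)))
}

test_that("the LPSO plan has fixed test composition and is
           deterministic", {
  plan <- make_lpso_plan(study_groups(), n_iterations = 10)
  it <- plan$iterations[[1]]
  expect_equal(it$seed, 42)
  grp <- study_groups()[it$test_subjects]
  expect_equal(sum(grp == "neutral"), 5)
  expect_equal(sum(grp == "risky"), 4)
  expect_length(it$train_subjects, 30)
  expect_equal(sum(study_groups()[it$train_subjects] == "neutral"), 16)
  expect_equal(sum(study_groups()[it$train_subjects] == "risky"), 14)
  plan2 <- make_lpso_plan(study_groups(), n_iterations = 10)
  expect_identical(plan, plan2)
  expect_gte(plan$p_percent, 20)
  expect_lte(plan$p_percent, 25)
})

test_that("the LPSO plan rejects degenerate subject pools", {
  few <- setNames(c(rep("neutral", 5), rep("risky", 4)),
                  paste0("S", 1:9))
  expect_error(make_lpso_plan(few), "too few")
})

test_that("no subject appears in both train and test of any iteration", {
  plan <- make_lpso_plan(study_groups())
  overlaps <- vapply(plan$iterations, function(it) {
    length(intersect(it$train_subjects, it$test_subjects))
  }, integer(1))
  expect_true(all(overlaps == 0))
  expect_equal(plan$seeds, 42:141)
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-counting
           estimator", {
  set.seed(16)
  for (i in 1:20) {
    n <- 50
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    s <- round(rnorm(n), 1)  # coarse scores force ties
    expect_equal(roc_auc_trapezoid(y, s), mw_auc(y, s), tolerance = 1e-10)
  }
  # perfect separation
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  s <- c(6:10, 1:5)
  expect_equal(roc_auc_trapezoid(y, s), 1)
  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(26)
  y2 <- runif(40) < 0.5
  s2 <- rnorm(40) + y2
  ref <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc_trapezoid(y2, s2), ref, tolerance = 1e-12)
})

test_that("weighted metrics follow the confusion-count definitions", {
  # TP=3, FP=1, FN=2, TN=4
  labels <- c(rep("risky", 5), rep("neutral", 5))
  pred <- c("risky", "risky", "risky", "neutral", "neutral",
            "risky", "neutral", "neutral", "neutral", "neutral")
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.6, 0.2, 0.1, 0.15, 0.05)
  met <- weighted_metrics(labels, pred, scores)
  expect_equal(met$accuracy, 0.7)
  expect_equal(c(met$tp, met$fp, met$fn, met$tn), c(3, 1, 2, 4))
  # hand-computed weighted precision/recall with w = (0.5, 0.5)
  prec_r <- 3 / 4; prec_n <- 4 / 6
  rec_r <- 3 / 5; rec_n <- 4 / 5
  expect_equal(met$precision, 0.5 * prec_r + 0.5 * prec_n)
  expect_equal(met$recall, 0.5 * rec_r + 0.5 * rec_n)
  f1_r <- 2 * prec_r * rec_r / (prec_r + rec_r)
  f1_n <- 2 * prec_n * rec_n / (prec_n + rec_n)
  expect_equal(met$f1, 0.5 * f1_r + 0.5 * f1_n)
  # all risky scored above all neutral -> weighted AUC 1
  perfect <- weighted_metrics(labels,
                              ifelse(labels == "risky", "risky", "neutral"),
                              c(5:1 + 10, 5:1))
  expect_equal(perfect$auc, 1)
})

test_that("class-weighted AUC equals the positive-class AUC for
           complementary scores", {
  set.seed(17)
  labels <- sample(c("risky", "neutral"), 60, replace = TRUE,
                   prob = c(0.4, 0.6))
  scores <- rnorm(60)
  met <- weighted_metrics(labels, ifelse(scores > 0, "risky", "neutral"),
                          scores)
  expect_equal(met$auc, roc_auc_trapezoid(labels == "risky", scores),
               tolerance = 1e-12)
})

test_that("confusion aggregation row-normalizes then averages", {
  m1 <- confusion_matrix(tp = 6, fp = 2, fn = 4, tn = 8)
  pct <- aggregate_confusion(list(m1))
  expect_equal(unname(pct["risky", ]), c(60, 40))
  expect_equal(unname(pct["neutral", ]), c(20, 80))
  # identical matrices: aggregate equals the single-iteration percentages
  expect_equal(aggregate_confusion(list(m1, m1, m1)), pct)
  # random confusions vs direct-averaging oracle
  set.seed(18)
  ms <- lapply(1:5, function(i) {
    confusion_matrix(sample(1:9, 1), sample(1:9, 1), sample(1:9, 1),
                     sample(1:9, 1))
  })
  oracle <- Reduce(`+`, lapply(ms, function(m) m / rowSums(m) * 100)) / 5
  expect_equal(aggregate_confusion(ms), oracle)
  expect_true(all(abs(rowSums(aggregate_confusion(ms)) - 100) < 1e-9))
})

test_that("the chance test calibrates to the analytic t distribution", {
  set.seed(19)
  strong <- rnorm(100, 0.6, 0.01)
  res <- significance_vs_chance(strong)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$stars, "***")
  expect_equal(res$p_value,
               t.test(strong, mu = 0.5, alternative = "greater")$p.value)
  expect_message(flat <- significance_vs_chance(rep(0.5, 100)),
                 "zero-variance")
  expect_equal(flat$p_value, 1)
  expect_equal(flat$stars, "")
  expect_error(significance_vs_chance(0.6), "at least 2")
  expect_equal(significance_stars(c(2e-2, 5e-4, 0.2)),
               c("*", "***", ""))
})

test_that("type-I error of the chance test is nominal for independent
           series", {
  set.seed(20)
  rejections <- mean(vapply(1:200, function(i) {
    significance_vs_chance(rnorm(100, 0.5, 0.05))$p_value < 0.05
  }, logical(1)))
  expect_lt(rejections, 0.1)
})

make_feature_set <- function(signal_sd = 0, n_per_subj = 30, seed = 22) {
  set.seed(seed)
  groups <- study_groups()
  meta <- data.frame(
    subject_id = rep(names(groups), each = n_per_subj),
    group = rep(unname(groups), each = n_per_subj),
    condition = "SH", stringsAsFactors = FALSE
  )
  x <- matrix(rnorm(nrow(meta) * 3), ncol = 3)
  if (signal_sd > 0) {
    x[, 1] <- x[, 1] * 0.1 + (meta$group == "risky")
  }
  nm <- taskbeta:::f216_names(9)
  feature_matrix(x, paste0("Pre_beta_", 1:3), "PBTST", meta,
                 rep("prefrontal", 3))
}

test_that("separable features give high accuracy for all four
           classifiers", {
  fm <- make_feature_set(signal_sd = 1, n_per_subj = 15)
  plan <- make_lpso_plan(study_groups(), n_iterations = 5)
  rep <- run_validation(fm, plan)
  acc <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_true(all(acc$mean > 0.9))
  auc <- rep$summary[rep$summary$metric == "auc", ]
  expect_true(all(auc$mean > 0.95))
})

test_that("validation reports are reproducible and track chance on
           pure noise", {
  fm <- make_feature_set(signal_sd = 0, n_per_subj = 10, seed = 23)
  plan <- make_lpso_plan(study_groups(), n_iterations = 20)
  rep1 <- run_validation(fm, plan, classifiers = c("lr", "svm"))
  rep2 <- run_validation(fm, plan, classifiers = c("lr", "svm"))
  expect_identical(rep1, rep2)
  auc <- rep1$summary[rep1$summary$metric == "auc", ]
  expect_true(all(abs(auc$mean - 0.5) < 0.15))
  expect_equal(nrow(rep1$per_iteration), 40)
})
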