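test_that("feature reduction preserves constants and fixes the layout", {
  tfr <- fixture_constant_tfr(value = 2.5)
  f216 <- reduce_to_f216(tfr)
  expect_equal(ncol(f216$values), 216)
  expect_true(all(f216$values == 2.5))
  expect_equal(f216$feature_names[1:9], paste0("Pre_delta_", 1:9))
  expect_equal(f216$feature_names[216], "O_beta_9")
  f24 <- reduce_to_f24(f216)
  expect_equal(ncol(f24$values), 24)
  expect_true(all(f24$values == 2.5))
})

test_that("a localized beta source maps only onto its feature cell", {
  tfr <- fixture_constant_tfr(value = 0)
  pre <- which(tfr$montage$region_of == "prefrontal")
  beta_bins <- which(tfr$freqs >= 13 & tfr$freqs < 30)
  tfr$psd[, pre[1], beta_bins, 3] <- 4
  f216 <- reduce_to_f216(tfr)
  nz <- which(colSums(f216$values) > 0)
  expect_equal(f216$feature_names[nz], "Pre_beta_3")
  # oracle: brute-force nested averaging over bins then channels
  oracle <- mean(tfr$psd[1, pre, beta_bins, 3])
  expect_equal(unique(f216$values[, nz]), oracle)
  expect_equal(oracle, 4 / length(pre))
})

test_that("band edges follow the half-open bin-center convention", {
  # fs = 256 puts grid points exactly on the integer band edges
  tfr <- fixture_constant_tfr(value = 0, fs = 256)
  bin4 <- which(abs(tfr$freqs - 4) < 1e-9)  # bin exactly at 4 Hz -> theta
  expect_true(length(bin4) == 1)
  tfr$psd[, , bin4, ] <- 1
  f216 <- reduce_to_f216(tfr)
  delta_cols <- grepl("_delta_", f216$feature_names)
  theta_cols <- grepl("_theta_", f216$feature_names)
  expect_true(all(f216$values[, delta_cols] == 0))
  expect_true(all(f216$values[, theta_cols] > 0))
})

test_that("window averaging to F24 matches direct summation", {
  set.seed(12)
  vals <- matrix(rexp(4 * 216), 4)
  f216 <- fixture_f216(vals)
  f24 <- reduce_to_f24(f216)
  # Pre_beta_1..9 = 1..9 averages to 5
  vals2 <- matrix(0, 2, 216)
  pb_cols <- match(paste0("Pre_beta_", 1:9), f216$feature_names)
  vals2[, pb_cols] <- matrix(1:9, 2, 9, byrow = TRUE)
  expect_equal(unname(reduce_to_f24(fixture_f216(vals2))$values[, "Pre_beta"]),
               c(5, 5))
  # oracle: independent loop
  for (key in c("Pre_delta", "C_alpha", "O_beta")) {
    cols <- match(paste0(key, "_", 1:9), f216$feature_names)
    expect_equal(unname(f24$values[, key]),
                 apply(vals[, cols], 1, function(r) sum(r) / 9))
  }
  expect_error(reduce_to_f24(f24), "F216")
})

test_that("the PBTST projection extracts the nine prefrontal beta
           features in window order", {
  vals <- matrix(0, 2, 216)
  pb_cols <- match(paste0("Pre_beta_", 1:9),
                   taskbeta:::f216_names(9)$names)
  vals[, pb_cols] <- matrix(1:9, 2, 9, byrow = TRUE)
  pb <- select_pbtst(fixture_f216(vals))
  expect_equal(ncol(pb$values), 9)
  expect_equal(pb$feature_names, paste0("Pre_beta_", 1:9))
  expect_equal(unname(pb$values[1, ]), as.numeric(1:9))
  expect_equal(pb$space_tag, "PBTST")
})

test_that("screening agrees with stats::t.test and is label-symmetric", {
  set.seed(13)
  n <- 40
  vals <- matrix(rnorm(n * 216), n)
  meta <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:8), each = 5),
    group = rep(c("neutral", "risky"), each = n / 2),
    condition = "SH", stringsAsFactors = FALSE
  )
  fm <- fixture_f216(vals, meta = meta)
  sr <- screen_features(fm, alpha = 0.05)
  for (j in c(1, 50, 216)) {
    ref <- t.test(vals[meta$group == "neutral", j],
                  vals[meta$group == "risky", j])
    expect_equal(sr$t_stats[[j]], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(sr$p_values[[j]], ref$p.value, tolerance = 1e-12)
  }
  # swapping labels flips t, leaves p/q/selection unchanged
  meta2 <- meta
  meta2$group <- ifelse(meta$group == "neutral", "risky", "neutral")
  sr2 <- screen_features(fixture_f216(vals, meta = meta2), alpha = 0.05)
  expect_equal(sr2$t_stats, -sr$t_stats)
  expect_equal(sr2$p_values, sr$p_values)
  expect_equal(sr2$selected, sr$selected)
  # BH q-values are non-decreasing in p-value rank
  ord <- order(sr$p_values)
  expect_true(all(diff(sr$q_values[ord]) > -1e-15))
})

test_that("screening flags planted shifts and tolerates constant
           features", {
  set.seed(14)
  n <- 400
  vals <- matrix(rnorm(n * 100), n)
  meta <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:8), length.out = n),
    group = rep(c("neutral", "risky"), each = n / 2),
    condition = "SH", stringsAsFactors = FALSE
  )
  vals[meta$group == "risky", 7] <- vals[meta$group == "risky", 7] + 5
  vals[, 8] <- 3  # constant: t undefined, p forced to 1
  nm <- taskbeta:::f216_names(9)
  fm <- feature_matrix(vals, nm$names[1:100], "F216", meta,
                       nm$regions[1:100])
  expect_message(sr <- screen_features(fm), "constant")
  expect_true(sr$selected[[7]])
  expect_lt(sr$q_values[[7]], 1e-3)
  expect_equal(sr$p_values[[8]], 1)
  expect_false(sr$selected[[8]])
})

test_that("subject-level screening aggregates trials before testing", {
  set.seed(15)
  meta <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:10), each = 20),
    group = rep(c("neutral", "risky"), each = 100),
    condition = "SH", stringsAsFactors = FALSE
  )
  vals <- matrix(rnorm(200 * 216), 200)
  fm <- fixture_f216(vals, meta = meta)
  sr <- screen_features(fm, unit = "subjects")
  # oracle for one feature
  subj_means <- tapply(vals[, 1], meta$subject_id, mean)
  grp <- tapply(meta$group, meta$subject_id, `[`, 1)
  ref <- t.test(subj_means[grp == "neutral"], subj_means[grp == "risky"])
  expect_equal(sr$p_values[[1]], ref$p.value, tolerance = 1e-12)
})

test_that("the ratio report reproduces the published worked examples", {
  mk <- function(pre_f, total) {
    structure(list(counts = list(
      total = total, pre_f = pre_f,
      ratio = if (total > 0) pre_f / total * 100 else 0)),
      class = "ScreeningResult")
  }
  tab <- ratio_report(list(ML = mk(3, 5), Rest24 = mk(4, 17),
                           SH216 = mk(27, 31), Rest216 = mk(15, 104),
                           none = mk(0, 6)))
  expect_equal(tab$Ratio, c(60, 23.53, 87.10, 14.42, 0))
  expect_equal(tab$PreF, c(3, 4, 27, 15, 0))
})

test_that("trial reordering commutes with feature reduction", {
  es <- generate_dataset(fixture_config(seed = 31))
  f <- f216_from_epochs(es)
  set.seed(32)
  perm <- sample(n_trials(es))
  es_perm <- es
  es_perm$data <- es$data[perm, , , drop = FALSE]
  es_perm$trials_meta <- es$trials_meta[perm, ]
  f2 <- f216_from_epochs(es_perm)
  expect_equal(f2$values, f$values[perm, ], tolerance = 1e-12)
})
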