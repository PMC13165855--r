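test_that("subject-mixed split stratifies, separates validation, and is seeded", {
  set.seed(1)
  labels <- rep(c(0L, 1L), each = 400)
  subjects <- rep(sprintf("S%d", 1:8), 100)
  sp <- make_subject_mixed_split(labels, subjects, 0.7, 0.1, seed = 3)
  f <- sp$folds[[1]]
  expect_length(f$test_idx, 240)
  expect_length(intersect(f$train_idx, f$test_idx), 0)
  expect_length(intersect(f$val_idx, f$test_idx), 0)
  expect_length(intersect(f$train_idx, f$val_idx), 0)
  expect_equal(sort(c(f$train_idx, f$val_idx, f$test_idx)), seq_len(800))
  # stratification within one sample of the global ratio
  expect_equal(sum(labels[f$test_idx] == 1L), 120)
  expect_equal(sum(labels[c(f$train_idx, f$val_idx)] == 1L), 280)
  # 8:2 split sizes
  sp2 <- make_subject_mixed_split(labels, subjects, 0.8, 0.1, seed = 3)
  expect_length(sp2$folds[[1]]$test_idx, 160)
  expect_length(c(sp2$folds[[1]]$train_idx, sp2$folds[[1]]$val_idx), 640)
  # determinism
  sp3 <- make_subject_mixed_split(labels, subjects, 0.7, 0.1, seed = 3)
  expect_identical(sp$folds, sp3$folds)
  expect_error(make_subject_mixed_split(rep(0L, 10), rep("a", 10)),
               "both classes")
})

test_that("LOSO folds cover every sample once with subject disjointness", {
  labels <- rep(c(0L, 1L), 30)
  subjects <- rep(sprintf("S%d", 1:5), each = 12)
  plan <- make_loso_folds(subjects, labels, seed = 2)
  expect_length(plan$folds, 5)
  all_test <- sort(unname(unlist(lapply(plan$folds, `[[`, "test_idx"))))
  expect_equal(all_test, seq_along(labels))   # each sample tested once
  for (f in plan$folds) {
    expect_length(intersect(f$test_idx, c(f$train_idx, f$val_idx)), 0)
    expect_false(f$subject %in% subjects[c(f$train_idx, f$val_idx)])
    expect_true(all(subjects[f$test_idx] == f$subject))
  }
  expect_error(make_loso_folds(rep("only", 4), rep(0:1, 2)), "at least 2")
  expect_length(make_loso_folds(rep(c("a", "b"), 6), labels[1:12])$folds, 2)
})

test_that("confusion metrics reproduce printed worked examples", {
  # aggregate LOSO confusion counts: sensitivity 84.8%, specificity 85.7%
  m <- confusion_metrics(confusion_matrix(tp = 890, fn = 160,
                                          fp = 150, tn = 900))
  expect_equal(round(m$sensitivity, 1), 84.8)
  expect_equal(round(m$specificity, 1), 85.7)
  expect_equal(m$accuracy, 100 * 1790 / 2100, tolerance = 1e-10)
  # 7 false alarms + 1 miss on 240 samples -> 3.33% error rate
  m2 <- confusion_metrics(confusion_matrix(tp = 119, fn = 1,
                                           fp = 7, tn = 113))
  expect_equal(round(m2$error_rate, 2), 3.33)
  # perfect predictions
  m3 <- confusion_metrics(confusion_counts(c(0, 1, 1), c(0, 1, 1)))
  expect_equal(m3$accuracy, 100)
  expect_equal(m3$f1, 100)
  # undefined ratios are NA, not zero
  m4 <- confusion_metrics(confusion_matrix(0, 0, 0, 5))
  expect_true(is.na(m4$precision))
  expect_true(is.na(m4$recall))
  # f1 is the harmonic mean of precision and recall
  m5 <- confusion_metrics(confusion_matrix(30, 10, 20, 40))
  expect_equal(m5$f1, 2 * m5$precision * m5$recall /
                 (m5$precision + m5$recall))
})

test_that("fold aggregation reports mean, sd, CI and the summed matrix", {
  cms <- list(confusion_matrix(8, 2, 0, 10), confusion_matrix(9, 1, 1, 9))
  fr <- aggregate_folds(c(80, 90), cms)
  expect_equal(fr$mean, 85)
  expect_equal(fr$aggregate_cm$tp, 17)
  expect_equal(fr$aggregate_cm$tn, 19)
  # aggregate-matrix accuracy equals the sample-weighted fold mean
  expect_equal(fr$aggregate_accuracy, 100 * 36 / 40)
  expect_equal(aggregate_folds(c(77, 77, 77))$sd, 0)
  set.seed(6)
  accs <- runif(21, 70, 95)
  fr2 <- aggregate_folds(accs)
  expect_equal(fr2$mean, sum(accs) / 21, tolerance = 1e-9)
  expect_equal(fr2$sd, sqrt(sum((accs - mean(accs))^2) / 20),
               tolerance = 1e-9)
  expect_equal(fr2$ci95, mean(accs) + c(-1, 1) * 1.96 * sd(accs) / sqrt(21),
               tolerance = 1e-9)
})

test_that("paired fold statistics match closed-form arithmetic", {
  b <- c(80, 82, 79, 85, 81)
  d <- c(1, 2, 3, 2.5, 0.5)   # tie-free so the signed-rank null is exact
  st <- paired_fold_tests(b + d, b)
  m <- mean(d); s <- sd(d)
  expect_equal(st$mean_diff, 1.8)
  expect_equal(st$t_stat, m / (s / sqrt(5)), tolerance = 1e-10)
  expect_equal(st$cohens_d, m / s, tolerance = 1e-10)
  # all differences positive, n = 5 -> exact signed-rank W = 15, p = 1/16
  expect_equal(st$wilcoxon_w, 15)
  expect_equal(st$wilcoxon_p, 0.0625, tolerance = 1e-10)
  expect_equal(st$flag, "ok")
  # identical vectors
  st0 <- paired_fold_tests(b, b)
  expect_equal(st0$t_stat, 0)
  expect_equal(st0$t_p, 1)
  expect_equal(st0$flag, "all_zero")
  # constant shift: zero-variance differences are flagged
  st1 <- paired_fold_tests(b + 1, b)
  expect_equal(st1$flag, "zero_variance")
  expect_true(is.infinite(st1$cohens_d))
  expect_error(paired_fold_tests(1:3, 4:6), ">= 5")
})

test_that("balanced subsetting honors per-subject quotas and seeds", {
  labels <- rep(c(0L, 1L), each = 60)
  subjects <- rep(rep(sprintf("S%d", 1:3), each = 20), 2)
  idx <- draw_balanced_subset(labels, subjects, per_class = 30, seed = 9)
  expect_length(idx, 60)
  expect_equal(sum(labels[idx] == 1L), 30)
  # each subject contributes at least floor(30/3) = 10 per class
  tab <- table(subjects[idx], labels[idx])
  expect_true(all(tab >= 10))
  expect_identical(idx, draw_balanced_subset(labels, subjects, 30, seed = 9))
  # stability harness with a deterministic majority-class stub
  rs <- resample_stability(labels, subjects,
                           run_fn = function(i, s) 50,
                           per_class = 30, seeds = c(100, 200, 300))
  expect_equal(rs$mean, 50)
  expect_equal(rs$sd, 0)
  expect_identical(rs$subsets[[1]],
                   draw_balanced_subset(labels, subjects, 30, 100))
  # scales down with a message when per_class exceeds availability
  expect_message(resample_stability(labels, subjects,
                                    run_fn = function(i, s) 50,
                                    per_class = 100,
                                    seeds = c(100, 200)),
                 "reduced")
})

test_that("kernel-weight summaries stay on the simplex per class", {
  cfg <- toy_config()
  b <- toy_batch(cfg, 8, seed = 71)
  inputs <- structure(list(Xtil = b$Xtil, G = b$G,
                           labels = rep(c(0L, 1L), 4),
                           subjects = rep("s", 8), n = 8, cfg = cfg),
                      class = "dcamnet_inputs")
  ks <- kernel_weight_summary(dcamnet_init(cfg, 3), inputs)
  expect_equal(rowSums(ks), c(alert = 1, fatigued = 1), tolerance = 1e-6)
  # K = 1 static: both class means are exactly [1]
  ks1 <- kernel_weight_summary(dcamnet_init(cfg, 3, "static_K1"), inputs)
  expect_equal(unname(ks1[, 1]), c(1, 1))
})
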