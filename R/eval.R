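#' Stratified subject-mixed split
#'
#' Segment-level stratified random split: class proportions are preserved
#' (within one sample) in the training and test sets, and a further
#' stratified validation carve-out is taken from the training portion only.
#' The same subject may appear on both sides — this is the upper-bound
#' protocol, by design.
#'
#' @param labels Integer 0/1 vector.
#' @param subjects Character vector (carried through for bookkeeping).
#' @param train_fraction Fraction of samples assigned to training
#'   (before the validation carve-out), default 0.7.
#' @param val_fraction Fraction of the training portion held out for
#'   validation, default 0.1.
#' @param seed Seed making the split reproducible.
#' @return A `split_plan` with one fold: `train_idx`, `val_idx`,
#'   `test_idx`.
#' @export
make_subject_mixed_split <- function(labels, subjects,
                                     train_fraction = 0.7,
                                     val_fraction = 0.1, seed = 0L) {
  stopifnot(length(labels) == length(subjects))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present")
  set.seed(seed)
  tr <- integer(0); te <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) stop("class ", cl, " has fewer than 2 samples")
    n_tr <- round(train_fraction * length(idx))
    pick <- sample(idx, n_tr)
    tr <- c(tr, pick)
    te <- c(te, setdiff(idx, pick))
  }
  val <- integer(0)
  for (cl in classes) {
    idx <- tr[labels[tr] == cl]
    n_val <- max(1L, round(val_fraction * length(idx)))
    val <- c(val, sample(idx, n_val))
  }
  tr <- setdiff(tr, val)
  structure(list(mode = "subject_mixed", seed = as.integer(seed),
                 folds = list(list(train_idx = sort(tr), val_idx = sort(val),
                                   test_idx = sort(te)))),
            class = "split_plan")
}

#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: the fold's test set is that subject's
#' samples; training uses all other subjects, with a stratified validation
#' carve-out taken from the training portion only (never from the held-out
#' subject).
#'
#' @param subjects Character vector of per-sample subject ids.
#' @param labels Integer 0/1 vector (used for the stratified carve-out).
#' @param val_fraction Validation fraction of each fold's training set.
#' @param seed Seed for the validation carve-outs.
#' @return A `split_plan` with one fold per subject (named by subject).
#' @export
make_loso_folds <- function(subjects, labels, val_fraction = 0.1,
                            seed = 0L) {
  stopifnot(length(labels) == length(subjects))
  subj <- unique(subjects)
  if (length(subj) < 2L) stop("LOSO requires at least 2 distinct subjects")
  set.seed(seed)
  folds <- lapply(subj, function(s) {
    te <- which(subjects == s)
    tr <- which(subjects != s)
    val <- integer(0)
    for (cl in sort(unique(labels[tr]))) {
      idx <- tr[labels[tr] == cl]
      n_val <- max(1L, round(val_fraction * length(idx)))
      val <- c(val, sample(idx, n_val))
    }
    list(train_idx = sort(setdiff(tr, val)), val_idx = sort(val),
         test_idx = sort(te), subject = s)
  })
  names(folds) <- subj
  structure(list(mode = "loso", seed = as.integer(seed), folds = folds),
            class = "split_plan")
}

#' Confusion matrix from labels and predictions
#'
#' @param truth,pred Integer 0/1 vectors (1 = fatigued, the positive
#'   class).
#' @return A `confusion_matrix` list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1L & pred == 1L),
                 fn = sum(truth == 1L & pred == 0L),
                 fp = sum(truth == 0L & pred == 1L),
                 tn = sum(truth == 0L & pred == 0L)),
            class = "confusion_matrix")
}

#' @rdname confusion_counts
#' @param tp,fn,fp,tn Non-negative counts (positive class = fatigued).
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall (= sensitivity of the fatigued class),
#' specificity, F1 (harmonic mean of precision and recall) and error rate,
#' all as percentages. A metric whose denominator is zero is returned as
#' `NA` (flagged undefined, never silently 0).
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report` list of percentages.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix")
  sdiv <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- sdiv(cm$tp + cm$tn, total)
  prec <- sdiv(cm$tp, cm$tp + cm$fp)
  rec <- sdiv(cm$tp, cm$tp + cm$fn)
  spec <- sdiv(cm$tn, cm$tn + cm$fp)
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 sensitivity = rec, specificity = spec, f1 = f1,
                 error_rate = 100 - acc, n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  ",
                     "F1 %.2f%%  specificity %.2f%%  (n = %d)\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$specificity, x$n))
  invisible(x)
}

#' Aggregate per-fold results
#'
#' Combines per-fold accuracies and confusion matrices into the three
#' aggregations reported for cross-validated runs: the unweighted mean and
#' standard deviation of fold accuracies with a normal-approximation 95%
#' confidence interval (`mean +/- 1.96 sd / sqrt(n)`), the summed aggregate
#' confusion matrix, and the accuracy recomputed from that aggregate
#' matrix (equal to the sample-weighted mean of fold accuracies).
#'
#' @param accs Numeric vector of per-fold accuracies (%).
#' @param cms Optional list of per-fold `confusion_matrix` objects.
#' @return A `fold_results` list.
#' @export
aggregate_folds <- function(accs, cms = NULL) {
  stopifnot(length(accs) >= 2L)
  m <- mean(accs)
  s <- stats::sd(accs)
  ci <- m + c(-1, 1) * 1.96 * s / sqrt(length(accs))
  agg <- NULL; agg_acc <- NA_real_
  if (!is.null(cms)) {
    agg <- confusion_matrix(sum(vapply(cms, `[[`, numeric(1), "tp")),
                            sum(vapply(cms, `[[`, numeric(1), "fn")),
                            sum(vapply(cms, `[[`, numeric(1), "fp")),
                            sum(vapply(cms, `[[`, numeric(1), "tn")))
    agg_acc <- confusion_metrics(agg)$accuracy
  }
  structure(list(accuracies = accs, mean = m, sd = s, ci95 = ci,
                 aggregate_cm = agg, aggregate_accuracy = agg_acc,
                 n_folds = length(accs)),
            class = "fold_results")
}

#' Paired fold-level statistics
#'
#' Two-sided paired t-test, Wilcoxon signed-rank test (exact null
#' distribution for n <= 25 folds with zero differences dropped, normal
#' approximation with continuity correction above) and paired Cohen's d
#' (`mean(diff) / sd(diff)`, denominator n - 1). Degenerate inputs —
#' all-zero differences or zero-variance differences — are flagged rather
#' than reported as spurious statistics.
#'
#' @param acc_a,acc_b Equal-length (>= 5) vectors of per-fold accuracies.
#' @return A `stat_test_result` list with `t_stat`, `t_p`, `wilcoxon_w`,
#'   `wilcoxon_p`, `cohens_d`, `mean_diff` and `flag` (`"ok"`,
#'   `"zero_variance"` or `"all_zero"`).
#' @export
paired_fold_tests <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 5L)
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(structure(list(t_stat = 0, t_p = 1, wilcoxon_w = NA_real_,
                          wilcoxon_p = NA_real_, cohens_d = NA_real_,
                          mean_diff = 0, flag = "all_zero"),
                     class = "stat_test_result"))
  }
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    # constant nonzero shift: t and d are unbounded
    wt <- suppressWarnings(stats::wilcox.test(
      acc_a, acc_b, paired = TRUE, exact = length(d) <= 25L))
    return(structure(list(t_stat = Inf * sign(mean(d)), t_p = 0,
                          wilcoxon_w = unname(wt$statistic),
                          wilcoxon_p = wt$p.value,
                          cohens_d = Inf * sign(mean(d)),
                          mean_diff = mean(d), flag = "zero_variance"),
                     class = "stat_test_result"))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(
    acc_a, acc_b, paired = TRUE, exact = length(d) <= 25L,
    correct = length(d) > 25L))
  structure(list(t_stat = unname(tt$statistic), t_p = tt$p.value,
                 wilcoxon_w = unname(wt$statistic),
                 wilcoxon_p = wt$p.value,
                 cohens_d = mean(d) / sd_d, mean_diff = mean(d),
                 flag = "ok"),
            class = "stat_test_result")
}

#' Run one subject-mixed experiment
#'
#' Splits, trains and evaluates a model on prepared inputs under the
#' subject-mixed protocol.
#'
#' @param inputs A `dcamnet_inputs` object.
#' @param model_cfg A [dcamnet_config()].
#' @param train_cfg A [train_config()].
#' @param variant Architecture variant.
#' @param train_fraction Train fraction of the stratified split.
#' @param split Optional precomputed `split_plan` (overrides
#'   `train_fraction`).
#' @return List with `fit`, `metrics` (a `metrics_report`), `cm`,
#'   `pred` and `split`.
#' @export
run_subject_mixed <- function(inputs, model_cfg,
                              train_cfg = train_config(),
                              variant = "full", train_fraction = 0.7,
                              split = NULL) {
  if (is.null(split)) {
    split <- make_subject_mixed_split(inputs$labels, inputs$subjects,
                                      train_fraction,
                                      train_cfg$val_fraction,
                                      seed = train_cfg$seed)
  }
  f <- split$folds[[1]]
  fit <- train_dcamnet(inputs, f$train_idx, f$val_idx, model_cfg,
                       train_cfg, variant)
  pr <- predict_dcamnet(fit$model, subset_inputs(inputs, f$test_idx))
  cm <- confusion_counts(inputs$labels[f$test_idx], pr$class)
  list(fit = fit, metrics = confusion_metrics(cm), cm = cm, pred = pr,
       split = split)
}

#' Run a leave-one-subject-out experiment
#'
#' Trains one model per fold (each subject held out once) and aggregates
#' per-fold accuracies and confusion matrices.
#'
#' @inheritParams run_subject_mixed
#' @return List with `folds` (per-fold list of subject, accuracy, cm,
#'   fit), `results` (a `fold_results`), and `per_subject` data frame.
#' @export
run_loso <- function(inputs, model_cfg, train_cfg = train_config(),
                     variant = "full") {
  plan <- make_loso_folds(inputs$subjects, inputs$labels,
                          train_cfg$val_fraction, seed = train_cfg$seed)
  folds <- lapply(plan$folds, function(f) {
    fit <- train_dcamnet(inputs, f$train_idx, f$val_idx, model_cfg,
                         train_cfg, variant)
    pr <- predict_dcamnet(fit$model, subset_inputs(inputs, f$test_idx))
    cm <- confusion_counts(inputs$labels[f$test_idx], pr$class)
    list(subject = f$subject, accuracy = confusion_metrics(cm)$accuracy,
         cm = cm, fit = fit)
  })
  accs <- vapply(folds, `[[`, numeric(1), "accuracy")
  res <- aggregate_folds(accs, lapply(folds, `[[`, "cm"))
  list(folds = folds, results = res,
       per_subject = data.frame(subject = vapply(folds, `[[`, character(1),
                                                 "subject"),
                                accuracy = accs))
}

#' Re-sampling stability experiment
#'
#' Draws several independent balanced subsets (equal per-subject quotas,
#' `floor(per_class / n_subjects)` per class per subject with the seeded
#' remainder draw), runs the supplied experiment function on each, and
#' reports the mean and standard deviation of the resulting accuracies.
#'
#' @param labels,subjects Per-sample label and subject vectors.
#' @param run_fn Function called as `run_fn(subset_idx, seed)` returning a
#'   single accuracy (%); typically wraps [run_subject_mixed()] on a
#'   subset of prepared inputs.
#' @param per_class Target samples per class in each subset; scaled down
#'   with a message when a class has fewer available.
#' @param seeds Seeds, one per repeat (defaults to
#'   `c(100, 200, 300, 400, 500)`).
#' @return List with `accuracies`, `mean`, `sd`, `subsets` (the index
#'   draws).
#' @export
resample_stability <- function(labels, subjects, run_fn, per_class = 400L,
                               seeds = c(100L, 200L, 300L, 400L, 500L)) {
  avail <- min(sum(labels == 0L), sum(labels == 1L))
  if (per_class > avail) {
    message("per_class reduced from ", per_class, " to ", avail,
            " (available per-class samples)")
    per_class <- avail
  }
  subsets <- lapply(seeds, function(s)
    draw_balanced_subset(labels, subjects, per_class, s))
  accs <- mapply(function(idx, s) run_fn(idx, s), subsets, seeds)
  list(accuracies = accs, mean = mean(accs), sd = stats::sd(accs),
       subsets = subsets)
}

#' Draw a balanced subset with equal subject representation
#'
#' Per class, each subject contributes `floor(per_class / n_subjects)`
#' samples; the remainder is filled by a seeded draw from the leftover
#' pool.
#'
#' @param labels,subjects Per-sample vectors.
#' @param per_class Samples per class in the subset.
#' @param seed Seed for the quota and remainder draws.
#' @return Sorted integer indices of the subset.
#' @export
draw_balanced_subset <- function(labels, subjects, per_class, seed = 0L) {
  set.seed(seed)
  out <- integer(0)
  subj <- unique(subjects)
  for (cl in c(0L, 1L)) {
    quota <- per_class %/% length(subj)
    picked <- integer(0)
    for (s in subj) {
      pool <- which(labels == cl & subjects == s)
      if (length(pool) < quota) {
        stop("subject ", s, " has only ", length(pool), " class-", cl,
             " samples; quota is ", quota)
      }
      picked <- c(picked, sample(pool, quota))
    }
    rest <- setdiff(which(labels == cl), picked)
    extra <- per_class - length(picked)
    if (extra > 0L) picked <- c(picked, sample(rest, extra))
    out <- c(out, picked)
  }
  sort(out)
}

#' Per-class mean kernel-attention weights
#'
#' Records the kernel-attention vector pi for every sample and averages it
#' per class; each class mean lies on the probability simplex (averaging
#' preserves it).
#'
#' @param model A trained `dcamnet_model`.
#' @param inputs A `dcamnet_inputs` with labels.
#' @return Matrix 2 x K with rows `alert`, `fatigued`.
#' @export
kernel_weight_summary <- function(model, inputs) {
  pr <- predict_dcamnet(model, inputs)
  lab <- inputs$labels
  out <- rbind(alert = colMeans(pr$pi[lab == 0L, , drop = FALSE]),
               fatigued = colMeans(pr$pi[lab == 1L, , drop = FALSE]))
  out
}

#' Single-band masking analysis
#'
#' Probes a trained network band by band: for each condition only one
#' filter-bank output is retained (the rest zeroed) and the masked tensors
#' are passed through the network without retraining. Requires inputs
#' prepared with `keep_multiband = TRUE`.
#'
#' @param model A trained `dcamnet_model`.
#' @param inputs `dcamnet_inputs` with cached multi-band tensors.
#' @param bands Band indices to test (default all).
#' @param band_names Optional names for the report.
#' @param adapt_bn Recompute the normalization statistics on each masked
#'   condition before evaluating (default TRUE; see [bn_adapt()]). The
#'   learned weights are never touched. Without adaptation a masked
#'   single-band input, whose scale is far below the training
#'   statistics, mostly probes normalization mismatch rather than the
#'   band's information content.
#' @return Data frame with columns `band`, `accuracy`, `f1`.
#' @export
band_masking_analysis <- function(model, inputs, bands = NULL,
                                  band_names = NULL, adapt_bn = TRUE) {
  if (is.null(inputs$multiband)) {
    stop("inputs were prepared without keep_multiband = TRUE")
  }
  nb <- model$cfg$Nb
  if (is.null(bands)) bands <- seq_len(nb)
  if (is.null(band_names)) {
    bn <- attr(inputs$multiband[[1]], "band_names")
    band_names <- if (!is.null(bn)) bn[bands] else as.character(bands)
  }
  rows <- lapply(seq_along(bands), function(j) {
    masked <- prepare_model_inputs(NULL, model$cfg, keep_bands = bands[j],
                                   multiband = inputs$multiband)
    masked$labels <- inputs$labels
    m_j <- if (isTRUE(adapt_bn)) bn_adapt(model, masked) else model
    pr <- predict_dcamnet(m_j, masked)
    mt <- confusion_metrics(confusion_counts(inputs$labels, pr$class))
    data.frame(band = band_names[j], accuracy = mt$accuracy, f1 = mt$f1)
  })
  do.call(rbind, rows)
}
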