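test_that("ROC/AUC matches hand enumeration and the Mann-Whitney statistic", {
  r <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(r$auc, 0.75)  # 3 of 4 pos/neg pairs won
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(utils::tail(r$roc$tpr, 1), 1)

  # perfectly separated and null scores
  expect_equal(roc_auc(rep(c(0, 1), each = 20),
                       c(runif(20, 0, 0.4), runif(20, 0.6, 1)))$auc, 1.0)
  set.seed(2)
  expect_lt(abs(roc_auc(sample(0:1, 10000, TRUE), runif(10000))$auc - 0.5), 0.02)

  set.seed(3)
  for (i in 1:300) {
    n <- sample(5:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    p <- round(runif(n), sample(1:3, 1))  # ties included
    expect_equal(roc_auc(y, p)$auc, mw_auc(y, p), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), class = "gaitfog_validation_error")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    y <- c(0, 1, sample(0:1, 48, TRUE))
    p <- runif(50)
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(y, p, quiet = TRUE, direction = "<", levels = c(0, 1)))))
    expect_equal(roc_auc(y, p)$auc, ref, tolerance = 1e-10)
  }
})

test_that("mean ROC averages vertically with population-SD bands", {
  mk <- function(win_score) {  # AUC = win_score / 10 by construction
    roc_auc(rep(c(0, 1), each = 10), c(1:10, rep(win_score + 0.5, 10)))
  }
  m <- mean_roc(list(mk(8), mk(9)))
  expect_equal(m$mean_auc, 0.85)
  expect_equal(m$sd_auc, 0.05)

  same <- mean_roc(list(mk(7), mk(7), mk(7)))
  expect_true(all(same$curve$sd_tpr == 0))
  expect_equal(same$mean_auc, 0.7)

  # envelope: the mean curve lies between fold-wise min and max TPR
  set.seed(4)
  rocs <- lapply(1:4, function(i) roc_auc(sample(0:1, 60, TRUE), runif(60)))
  m2 <- mean_roc(rocs)
  grid <- m2$curve$fpr
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$roc$fpr, r$roc$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(length(grid)))
  expect_true(all(m2$curve$mean_tpr >= apply(tprs, 1, min) - 1e-12))
  expect_true(all(m2$curve$mean_tpr <= apply(tprs, 1, max) + 1e-12))
  expect_error(mean_roc(rocs[1]), class = "gaitfog_validation_error")
})

test_that("the geometric-mean threshold maximizes sqrt(TPR x TNR)", {
  # operating points (0.1, 0.7), (0.2, 0.9), (0.4, 0.95): middle one wins
  expect_equal(sqrt(0.7 * 0.9), 0.7937, tolerance = 1e-4)
  expect_equal(sqrt(0.9 * 0.8), 0.8485, tolerance = 1e-4)
  expect_equal(sqrt(0.95 * 0.6), 0.7550, tolerance = 1e-4)

  set.seed(6)
  y <- c(rep(1, 40), rep(0, 60))
  p <- c(rbeta(40, 4, 2), rbeta(60, 2, 4))
  choice <- gmean_threshold(y, p)
  # exhaustive oracle over all candidate thresholds
  cands <- sort(unique(p))
  gm <- vapply(cands, function(tau) {
    pred <- p >= tau
    sqrt(mean(pred[y == 1]) * mean(!pred[y == 0]))
  }, numeric(1))
  expect_equal(choice$gmean, max(gm), tolerance = 1e-12)
  expect_equal(choice$gmean,
               sqrt(choice$sensitivity * choice$specificity), tolerance = 1e-12)
  # returned threshold reproduces the maximizing confusion
  cm <- confusion_metrics(y, p, choice$threshold)
  expect_equal(sqrt(cm$sensitivity * cm$specificity), max(gm), tolerance = 1e-12)

  # perfect classifier: g-mean 1 at a separating threshold
  perfect <- gmean_threshold(rep(c(0, 1), each = 5),
                             c(seq(0.1, 0.3, length = 5), seq(0.7, 0.9, length = 5)))
  expect_equal(perfect$gmean, 1)
})

test_that("confusion metrics follow the standard identities", {
  y <- rep(c(1, 0), c(100, 100))
  p <- c(rep(0.9, 85), rep(0.1, 15), rep(0.9, 32), rep(0.1, 68))
  m <- confusion_metrics(y, p, 0.5)
  expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]),
               c(tp = 85, fp = 32, tn = 68, fn = 15))
  expect_equal(m$sensitivity, 0.85)
  expect_equal(m$specificity, 0.68)
  expect_equal(m$precision, 0.726, tolerance = 1e-3)
  expect_equal(m$f_score, 0.783, tolerance = 1e-3)
  expect_equal(m$f_score,
               2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))

  all_pos <- confusion_metrics(y, p, 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  none <- confusion_metrics(y, p, 1.1)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$f_score))

  set.seed(8)
  for (i in 1:20) {
    yy <- sample(0:1, 50, TRUE)
    pp <- runif(50)
    mm <- confusion_metrics(yy, pp, runif(1))
    expect_equal(mm$tp + mm$fp + mm$tn + mm$fn, 50)
    if (!is.na(mm$f_score)) {
      expect_equal(mm$f_score, 2 * mm$precision * mm$sensitivity /
                     (mm$precision + mm$sensitivity))
    }
  }
})

test_that("the stratified hold-out split balances FOG occurrence", {
  tab <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                        fog_pct = c(0, 0, 2, 4, 6, 8, 10, 14, 20, 30))
  sp <- holdout_split(tab, 0.2, seed = 1)
  expect_length(sp$holdout_subjects, 2)
  expect_length(intersect(sp$train_subjects, sp$holdout_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$holdout_subjects), tab$subject_id)

  # degenerate stratification: identical FOG% still splits 20%
  flat <- tibble::tibble(subject_id = sprintf("S%02d", 1:10), fog_pct = rep(5, 10))
  expect_length(holdout_split(flat, 0.2, seed = 3)$holdout_subjects, 2)

  expect_error(holdout_split(tab[1:4, ], 0.2, 1), class = "gaitfog_validation_error")

  # over many seeds the hold-out mean FOG% tracks the cohort mean
  big <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                        fog_pct = c(rep(0, 4), seq(1, 30, length.out = 16)))
  means <- vapply(1:200, function(s) {
    h <- holdout_split(big, 0.2, seed = s)$holdout_subjects
    mean(big$fog_pct[big$subject_id %in% h])
  }, numeric(1))
  expect_lt(abs(mean(means) - mean(big$fog_pct)), 2)
})

test_that("grouped k-fold partitions subjects into near-equal folds", {
  subjects <- sprintf("P%02d", 1:54)
  folds <- grouped_kfold(subjects, k = 5, seed = 2)
  expect_equal(sort(vapply(folds, length, integer(1))), c(10, 11, 11, 11, 11))
  expect_setequal(unlist(folds), subjects)
  expect_equal(anyDuplicated(unlist(folds)), 0)
  expect_error(grouped_kfold(subjects[1:3], k = 5), class = "gaitfog_validation_error")
  expect_identical(grouped_kfold(subjects, 5, seed = 2),
                   grouped_kfold(subjects, 5, seed = 2))
})

test_that("selection prefers fewer sensors on exact AUC ties", {
  tab <- tibble::tibble(
    sensor_config = c("six_legs_feet", "lower_legs", "lumbar"),
    n_sensors = c(6, 2, 1),
    mean_auc = c(0.87, 0.87, 0.79),
    sd_auc = 0.05)
  expect_identical(gaitfog:::select_best_config(tab), "lower_legs")
  tab$mean_auc[3] <- 0.90
  expect_identical(gaitfog:::select_best_config(tab), "lumbar")
})
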