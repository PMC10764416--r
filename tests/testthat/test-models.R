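test_that("balanced class weights equalize the weighted class counts", {
  w <- compute_class_weights(rep(c("NEG", "POS"), c(90, 10)))
  expect_equal(unname(w), c(100 / 180, 100 / 20))
  expect_equal(unname(compute_class_weights(rep(c(0, 1), each = 50))), c(1, 1))
  expect_error(compute_class_weights(rep("NEG", 10)),
               class = "gaitfog_validation_error")
  # weighted counts equal
  expect_equal(90 * w[["NEG"]], 10 * w[["POS"]])
})

test_that("MiniRocket PPV features match brute-force convolution", {
  # single kernel / dilation / bias on a 12-sample toy series
  x <- c(0.4, -1.2, 2.1, 0.3, -0.6, 1.8, -2.4, 0.9, 1.1, -0.2, 0.5, -1.5)
  brute_ppv <- function(x, pos, d, bias) {
    T_len <- length(x)
    w <- rep(-1, 9); w[pos + 1] <- 2
    conv <- vapply(seq_len(T_len), function(t) {
      idx <- t + (0:8 - 4) * d
      xv <- ifelse(idx >= 1 & idx <= T_len, x[pmax(pmin(idx, T_len), 1)], 0)
      sum(w * xv)
    }, numeric(1))
    mean(conv > bias)
  }
  for (case in list(list(pos = c(0L, 4L, 8L), d = 1L, bias = 0.5),
                    list(pos = c(1L, 2L, 3L), d = 2L, bias = -1),
                    list(pos = c(0L, 1L, 8L), d = 3L, bias = 2))) {
    got <- gaitfog:::cpp_mr_transform(
      array(x, c(12, 1, 1)), matrix(case$pos, 1), case$d, 1L,
      list(0L), 0L, case$bias)
    expect_equal(got[1, 1], brute_ppv(x, case$pos, case$d, case$bias))
  }

  # randomized cases, multichannel (channel subsets sum before convolving)
  set.seed(17)
  for (i in 1:30) {
    T_len <- sample(15:40, 1)
    C <- sample(1:3, 1)
    xs <- matrix(rnorm(T_len * C), T_len, C)
    chans <- sort(sample(seq_len(C), sample(C, 1))) - 1L
    pos <- sort(sample(0:8, 3))
    d <- sample(1:3, 1)
    bias <- rnorm(1)
    got <- gaitfog:::cpp_mr_transform(
      array(xs, c(T_len, C, 1)), matrix(as.integer(pos), 1), as.integer(d),
      1L, list(chans), 0L, bias)
    expect_equal(got[1, 1],
                 brute_ppv(rowSums(xs[, chans + 1, drop = FALSE]), pos, d, bias))
  }

  # all-zero windows with positive bias give all-zero features
  zero_w <- gaitfog:::new_fog_windows(
    array(0, c(120, 3, 4)),
    tibble::tibble(subject_id = "S", trial_id = "T", start_s = 0:3,
                   fog_fraction = c(0, 0, 1, 1),
                   label = c("NEG", "NEG", "POS", "POS")),
    channel_names("lumbar"), "train")
  tf <- minirocket_fit(zero_w, minirocket_config(), seed = 1)
  tf$biases <- abs(tf$biases) + 0.1
  expect_true(all(minirocket_transform(tf, zero_w) == 0))
})

test_that("MiniRocket feature count realizes the 10,000 budget as 84 x 119", {
  w <- small_split()$train
  tf <- minirocket_fit(w, minirocket_config(), seed = 2)
  expect_equal(tf$n_features, 9996)
  expect_equal(tf$n_features, 84 * floor(10000 / 84))
  expect_true(all(tf$dilations <= 32))
  expect_lte(length(tf$dilations), 32)
  feats <- minirocket_transform(tf, small_split()$val)
  expect_equal(ncol(feats), 9996)
  expect_true(all(feats >= 0 & feats <= 1))
})

test_that("PPV features are invariant to amplitude scaling when biases refit", {
  w <- small_split()$val
  w_scaled <- w
  w_scaled$x <- w$x * 3.7
  cfg <- minirocket_config(feature_budget = 840L)  # small budget for speed
  f1 <- minirocket_transform(minirocket_fit(w, cfg, seed = 4), w)
  f2 <- minirocket_transform(minirocket_fit(w_scaled, cfg, seed = 4), w_scaled)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("the CNN learns a separable task, deterministically", {
  sp <- small_split()
  m <- train_cnn(sp$train, cnn_config(), seed = 7)
  p <- predict_proba(m, sp$val)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  expect_gte(roc_auc(p$label, p$prob)$auc, 0.90)
  expect_gt(mean(p$prob[p$label == "POS"]), mean(p$prob[p$label == "NEG"]))

  m2 <- train_cnn(sp$train, cnn_config(), seed = 7)
  expect_identical(m$state, m2$state)
  p1 <- predict_proba(m, sp$val, batch_size = 1L)
  expect_equal(p1$prob, p$prob, tolerance = 1e-12)

  expect_error(predict_proba(m, select_sensors(small_windows(), "lumbar")),
               class = "gaitfog_validation_error")
})

test_that("shuffled labels collapse the CNN to chance", {
  sp <- small_split()
  shuf <- sp$train
  set.seed(5)
  shuf$info$label <- sample(shuf$info$label)
  m <- train_cnn(shuf, cnn_config(epochs = 10L), seed = 7)
  p <- predict_proba(m, sp$val)
  auc <- roc_auc(p$label, p$prob)$auc
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("InceptionTime trains, ensembles by averaging, and admits size 1", {
  sp <- small_split()
  cfg <- inception_config(n_ensemble = 2L, bottleneck = 8L, n_filters = 8L,
                          epochs = 6L)
  m <- train_inceptiontime(sp$train, cfg, seed = 3)
  p <- predict_proba(m, sp$val)
  expect_gte(roc_auc(p$label, p$prob)$auc, 0.85)

  member <- gaitfog:::inception_member_probs(m, sp$val)
  expect_equal(ncol(member), 2)
  expect_equal(rowMeans(member), p$prob, tolerance = 1e-12)

  cfg1 <- inception_config(n_ensemble = 1L, bottleneck = 8L, n_filters = 8L,
                           epochs = 2L)
  m1 <- train_inceptiontime(sp$train, cfg1, seed = 3)
  p1 <- predict_proba(m1, sp$val)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_error(inception_config(n_ensemble = 0), class = "gaitfog_validation_error")
})

test_that("MiniRocket end-to-end learns and exposes one coefficient per feature", {
  sp <- small_split()
  m <- train_minirocket(sp$train, minirocket_config(), seed = 9)
  expect_length(m$state$head$w, m$state$transformer$n_features)
  expect_equal(n_parameters(m), 9996 + 1)
  p <- predict_proba(m, sp$val)
  expect_gte(roc_auc(p$label, p$prob)$auc, 0.85)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  co <- tidy(m)
  expect_equal(nrow(co), 9997)

  expect_error(minirocket_transform(list(), sp$val), class = "gaitfog_state_error")
  expect_error(train_minirocket(gaitfog:::subset_windows(
    sp$train, sp$train$info$label == "NEG")), class = "gaitfog_validation_error")
})

test_that("every family is a pure function of (data, config, seed)", {
  sp <- small_split()
  lab <- sp$train$info$label
  keep <- c(head(which(lab == "NEG"), 120), head(which(lab == "POS"), 80))
  few <- gaitfog:::subset_windows(sp$train, seq_along(lab) %in% keep)

  cfg_mr <- minirocket_config(feature_budget = 840L, head_epochs = 2L)
  m1 <- train_minirocket(few, cfg_mr, seed = 5)
  m2 <- train_minirocket(few, cfg_mr, seed = 5)
  expect_identical(m1$state$head$w, m2$state$head$w)
  expect_identical(m1$state$transformer$biases, m2$state$transformer$biases)
  m3 <- train_minirocket(few, cfg_mr, seed = 6)
  expect_false(identical(m1$state$head$w, m3$state$head$w))

  cfg_it <- inception_config(n_ensemble = 1L, bottleneck = 4L, n_filters = 4L,
                             epochs = 1L)
  i1 <- train_inceptiontime(few, cfg_it, seed = 5)
  i2 <- train_inceptiontime(few, cfg_it, seed = 5)
  expect_identical(i1$state, i2$state)
})

test_that("glance() summarizes fitted models", {
  sp <- small_split()
  m <- train_cnn(sp$train, cnn_config(epochs = 1L), seed = 1)
  g <- glance(m)
  expect_identical(g$family, "cnn")
  expect_equal(g$n_channels, 6)
  expect_gt(g$n_parameters, 1000)
})
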