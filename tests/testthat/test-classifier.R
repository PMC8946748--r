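# Balanced training sets, network training/inference, FPR estimation.

mk_class_matrix <- function(center, n, sd = 0.08) {
  m <- matrix(rep(center, n), n, byrow = TRUE) +
    matrix(rnorm(n * length(center), sd = sd), n)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

test_that("balancing emits exactly 5,500 per class with a 5,000/500 split", {
  set.seed(20)
  ex <- list(big = mk_class_matrix(runif(12), 10000),
             small = mk_class_matrix(runif(12), 800))
  bs <- build_balanced_set(ex, training_config(), seed = 1)
  expect_equal(bs$counts$n_total, c(5500, 5500))
  expect_equal(bs$counts$n_train_partition, c(5000, 5000))
  expect_equal(bs$counts$n_test, c(500, 500))
  expect_equal(bs$counts$n_fit, c(4000, 4000))
  expect_equal(bs$counts$n_val, c(1000, 1000))
  expect_equal(bs$counts$n_augmented, c(0, 4700))
  expect_equal(unname(table(bs$train$y) + table(bs$val$y) + table(bs$test$y)),
               unname(table(factor(c("big", "small"))) * 0 + 5500))
  expect_true(all(bs$train$x >= 0 & bs$train$x <= 1))
})

test_that("an empty class is an error naming the class", {
  ex <- list(ok = mk_class_matrix(runif(5), 10),
             void = matrix(numeric(0), 0, 5))
  expect_error(build_balanced_set(ex, training_config(20, 15, 5)), "void")
})

test_that("bin features are fixed-length blocks in [0, 1]", {
  set.seed(21)
  bss <- planted_summaries(c(20, 50), c(5, 5))
  x <- bin_features(bss)
  expect_equal(ncol(x), 500)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(apply(x[, 1:200], 1, max), rep(1, 10))   # spectrum block
  expect_equal(apply(x[, 201:300], 1, max), rep(1, 10)) # ICI block
})

test_that("the network separates linearly separable classes near-perfectly", {
  set.seed(22)
  centers <- list(A = runif(40), B = runif(40), C = runif(40))
  ex <- lapply(centers, mk_class_matrix, n = 260)
  bs <- build_balanced_set(ex, training_config(240, 200, 40), seed = 1)
  spec <- network_spec(hidden = c(64, 64, 64, 64), max_epochs = 40,
                       patience = 10)
  m <- train_network(bs, spec, seed = 2)
  probs <- mlp_forward(m, bs$test$x)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  acc <- mean(m$classes[max.col(probs)] == as.character(bs$test$y))
  expect_gt(acc, 0.99)
})

test_that("permuted-label training collapses to chance accuracy", {
  set.seed(23)
  centers <- list(A = runif(40), B = runif(40), C = runif(40))
  ex <- lapply(centers, mk_class_matrix, n = 120)
  bs <- build_balanced_set(ex, training_config(110, 90, 20), seed = 1)
  bs$train$y <- sample(bs$train$y)
  bs$val$y <- sample(bs$val$y)
  m <- train_network(bs, network_spec(hidden = c(64, 64), max_epochs = 20,
                                      patience = 20), seed = 3)
  probs <- mlp_forward(m, bs$test$x)
  acc <- mean(m$classes[max.col(probs)] == as.character(bs$test$y))
  expect_lt(acc, 0.55)  # chance is 1/3
})

test_that("a many-class spectral corpus beats the random baseline tenfold", {
  set.seed(24)
  tpl <- click_type_templates()
  # 14 catalog types + 6 synthetic confounder classes = 20 classes; the
  # spectrum block alone cannot separate same-peak types (Zc and UD38 both
  # peak at 38.5 kHz), so the click-rate block carries each type's modal ICI
  centers <- c(
    lapply(seq_len(nrow(tpl)), function(i) {
      s <- bump_spectrum(tpl$peak_freq_khz[i],
                         width_khz = tpl$bw3db_khz[i] / 1.665)
      ici <- numeric(100)
      ici[ceiling(tpl$modal_ici_s[i] * 100)] <- 0.9
      c((s - min(s)) / diff(range(s)), ici)
    }),
    lapply(seq(12, 92, by = 16), function(f0) {
      s <- bump_spectrum(f0, width_khz = 0.8)  # narrowband noise-like
      c((s - min(s)) / diff(range(s)), rep(0.1, 100))
    })
  )
  names(centers) <- c(tpl$name, paste0("noise", 1:6))
  ex <- lapply(centers, mk_class_matrix, n = 90, sd = 0.05)
  bs <- build_balanced_set(ex, training_config(80, 64, 16), seed = 1)
  m <- train_network(bs, network_spec(hidden = c(128, 128), max_epochs = 30,
                                      patience = 10), seed = 4)
  probs <- mlp_forward(m, bs$test$x)
  pred <- m$classes[max.col(probs)]
  per_class <- vapply(m$classes, function(cl)
    mean(pred[bs$test$y == cl] == cl), numeric(1))
  expect_true(all(per_class >= 10 * 1 / length(m$classes)))
})

test_that("prediction bookkeeping: empty input, feature mismatch, probabilities", {
  set.seed(25)
  ex <- list(A = mk_class_matrix(runif(500), 40),
             B = mk_class_matrix(runif(500), 40))
  bs <- build_balanced_set(ex, training_config(30, 24, 6), seed = 1)
  m <- train_network(bs, network_spec(hidden = c(32), max_epochs = 5,
                                      patience = 5), seed = 1)
  empty <- predict_bins(m, matrix(numeric(0), 0, 500))
  expect_equal(nrow(empty), 0)
  expect_error(predict_bins(m, matrix(0.5, 3, 499)), "feature length")
  bss <- planted_summaries(c(20, 60), c(3, 3))
  out <- predict_bins(m, bss)
  expect_equal(nrow(out), 6)
  expect_true(all(abs(rowSums(attr(out, "probs")) - 1) < 1e-6))
})

test_that("held-out planted bins are labeled with their own class", {
  set.seed(26)
  train_bss <- planted_summaries(c(20, 45, 70), c(40, 40, 40))
  test_bss <- planted_summaries(c(20, 45, 70), c(10, 10, 10))
  x <- bin_features(train_bss)
  truth <- rep(c("low", "mid", "high"), c(40, 40, 40))
  ex <- split.data.frame(x, truth)
  ex <- lapply(ex, as.matrix)
  bs <- build_balanced_set(ex, training_config(44, 36, 8), seed = 1)
  m <- train_network(bs, network_spec(hidden = c(64, 64), max_epochs = 25,
                                      patience = 10), seed = 5)
  out <- predict_bins(m, test_bss)
  want <- rep(c("low", "mid", "high"), c(10, 10, 10))
  expect_gte(mean(out$class == want), 0.9)
})

test_that("review artifacts sort by peak frequency and masks remove exactly k", {
  set.seed(27)
  n <- 25
  peaks <- sample(10:80, n, replace = TRUE)
  spectra <- do.call(rbind, lapply(peaks, bump_spectrum))
  labels <- data.frame(bin_start = seq_len(n) * 300, class = "UD28")
  path <- tempfile(fileext = ".png")
  mask <- rep(FALSE, n)
  mask[sample(n, 7)] <- TRUE
  res <- review_labels(labels, spectra, path, mask)
  expect_true(file.exists(path))
  expect_false(is.unsorted(peaks[res$order]))
  expect_equal(sum(res$labels$review_flag == "removed"), 7)
  res2 <- review_labels(labels, spectra)
  expect_true(all(res2$labels$review_flag == "kept"))
})

test_that("FPR arithmetic, stratification and unbiasedness behave", {
  # exact arithmetic
  lab <- data.frame(class = rep("A", 50),
                    truth = c(rep("A", 45), rep("B", 5)))
  est <- estimate_fpr(lab, n_per_stratum = 50, seed = 1)
  expect_equal(est$fpr, 0.10)
  est0 <- estimate_fpr(data.frame(class = "A", truth = "A"), 10)
  expect_equal(est0$fpr, 0)
  # stratified subsample close to the exhaustive rate
  set.seed(28)
  n <- 2000
  big <- data.frame(class = sample(c("A", "B"), n, replace = TRUE),
                    site = sample(c("S1", "S2"), n, replace = TRUE))
  big$truth <- ifelse(runif(n) < 0.15, "X", big$class)
  exact <- aggregate(list(fpr = big$class != big$truth),
                     by = list(class = big$class), FUN = mean)
  est <- estimate_fpr(big, n_per_stratum = 200, seed = 2)
  pooled <- aggregate(list(fpr = est$fpr), by = list(class = est$class),
                      FUN = mean)
  expect_true(all(abs(pooled$fpr - exact$fpr) <= 0.05))
  # unbiasedness across seeds
  means <- rowMeans(vapply(1:100, function(sd)
    aggregate(list(fpr = estimate_fpr(big, 100, seed = sd)$fpr),
              by = list(class = est$class), FUN = mean)$fpr,
    numeric(2)))
  expect_true(all(abs(means - exact$fpr) <= 0.02))
})

test_that("threshold sweeps retain everything at (0,0) and decrease monotonically", {
  set.seed(29)
  n <- 600
  lab <- data.frame(class = "A",
                    rl_db = runif(n, 115, 135),
                    n_clicks = rpois(n, 40))
  # contaminate low-RL bins with wrong labels
  lab$truth <- ifelse(lab$rl_db < 122 & runif(n) < 0.5, "B", "A")
  sw <- threshold_sweep(lab, rl_grid = c(0, 120, 125, 130),
                        clicks_grid = c(0, 20, 40))
  base <- sw[sw$min_rl_db == 0 & sw$min_clicks == 0, ]
  expect_equal(base$retention, 1.0)
  for (cg in unique(sw$min_clicks)) {
    ret <- sw$retention[sw$min_clicks == cg][order(unique(sw$min_rl_db))]
    expect_true(all(diff(ret) <= 0))
  }
  strict <- sw[sw$min_rl_db == 130 & sw$min_clicks == 40, ]
  expect_lte(strict$fpr, base$fpr)
})
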