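fake_fit <- function(Q, P, path, n, pi = 0.1, alpha = 3) {
  params <- hmm_params(rep(1 / 3, 3), Q, pi, alpha, P)
  structure(list(params = params,
                 posteriors = matrix(1 / 3, n, 3),
                 viterbi_path = path,
                 state_order = identify_state_roles(params)),
            class = "hmm_fit")
}

test_that("the five features are read off the fit as documented", {
  Q <- rbind(c(0.9, 0.08, 0.02), c(0.1, 0.8, 0.1), c(0.15, 0.25, 0.6))
  P <- rbind(c(1, 1, 1) / 3, c(1, 4, 4) / 9, c(1, 12, 12) / 25)
  n <- 100
  set.seed(51)
  counts <- cbind(rpois(n, 3), rpois(n, 4), rpois(n, 4))
  cm <- count_matrix(window_grid(c(chr1 = n * 300), 300), counts,
                     c("control", "chip", "chip"))
  # all windows called low: no targets
  f_low <- qc_features(fake_fit(Q, P, rep(1L, n), n), cm)
  expect_equal(unname(f_low["target_fraction"]), 0)
  expect_equal(unname(f_low["q_high_to_low"]), 0.15)
  # min_snr is the smallest high/medium mean-rate ratio over replicates
  rates_med <- 3 * c(4, 4) / 9 / (1 / 9)
  rates_high <- 3 * c(12, 12) / 25 / (1 / 25)
  expect_equal(unname(f_low["min_snr"]), min(rates_high / rates_med))
  # identical replicate columns: correlation exactly 1
  cm_id <- count_matrix(cm$grid, counts[, c(1, 2, 2)],
                        c("control", "chip", "chip"))
  f_id <- qc_features(fake_fit(Q, P, rep(1L, n), n), cm_id)
  expect_equal(unname(f_id["replicate_correlation"]), 1)
  # single replicate: sentinel 1 with warning
  cm_one <- count_matrix(cm$grid, counts[, 1:2], c("control", "chip"))
  expect_warning(f_one <- qc_features(fake_fit(Q, P, rep(1L, n), n), cm_one),
                 "single replicate")
  expect_equal(unname(f_one["replicate_correlation"]), 1)
})

test_that("variance explained by called states follows the one-way decomposition", {
  n <- 6L
  counts <- cbind(rep(2L, n), c(1L, 1L, 5L, 5L, 9L, 9L), c(1L, 1L, 5L, 5L, 9L, 9L))
  cm <- count_matrix(window_grid(c(chr1 = n * 300), 300), counts,
                     c("control", "chip", "chip"))
  Q <- matrix(1 / 3, 3, 3)
  P <- rbind(c(1, 1, 1) / 3, c(1, 4, 4) / 9, c(1, 12, 12) / 25)
  # states perfectly partition the response: everything explained
  f <- qc_features(fake_fit(Q, P, rep(1:3, each = 2), n), cm)
  expect_equal(unname(f["var_explained"]), 1)
  # grouping with identical per-group means: nothing explained
  f2 <- qc_features(fake_fit(Q, P, c(1L, 2L, 3L, 3L, 2L, 1L), n), cm)
  expect_equal(unname(f2["var_explained"]), 0)
})

test_that("corpus generation is balanced, deterministic and distributionally sane", {
  t1 <- suppressMessages(build_training_corpus(10, 10, seed = 61,
                                               n_windows = 600))
  expect_equal(nrow(t1), 20L)
  expect_equal(as.integer(table(t1$label)), c(10L, 10L))
  t2 <- suppressMessages(build_training_corpus(10, 10, seed = 61,
                                               n_windows = 600))
  expect_identical(t1, t2)
  # enrichment-free negatives sit near snr 1 or call almost nothing
  neg <- t1[t1$label == "fail", ]
  pos <- t1[t1$label == "pass", ]
  expect_gt(mean(pos$min_snr), mean(neg$min_snr))
  expect_gt(mean(pos$replicate_correlation), mean(neg$replicate_correlation))
})

test_that("the SVM separates clean classes and honours fold constraints", {
  set.seed(71)
  n <- 40
  pos <- data.frame(a = rnorm(n, 3), b = rnorm(n, 3))
  neg <- data.frame(a = rnorm(n, -3), b = rnorm(n, -3))
  corpus <- rbind(cbind(pos, label = "pass"), cbind(neg, label = "fail"))
  corpus$label <- factor(corpus$label, levels = c("fail", "pass"))
  m <- train_qc(corpus, folds = 10, seed = 71)
  expect_equal(m$cv_accuracy, 1.0)
  # shuffled labels: near chance
  sh <- corpus
  set.seed(72)
  sh$label <- sample(sh$label)
  ms <- train_qc(sh, folds = 10, seed = 71)
  expect_gte(ms$cv_accuracy, 0.3)
  expect_lte(ms$cv_accuracy, 0.7)
  expect_error(train_qc(corpus, folds = 1), "at least 2")
  tiny <- corpus[c(1:3, 41:43), ]
  expect_error(train_qc(tiny, folds = 10, seed = 1), "stratified")
})

test_that("verdicts are deterministic and catch failed immunoprecipitation", {
  model <- cached_qc_model()
  expect_gte(model$cv_accuracy, 0.9)
  # a clean enriched simulation is accepted
  sim <- simulate_chip(sim_config(n_windows = 3000, n_chrom = 1, seed = 5100))
  dp <- discretize(sim$counts, qc_model = model)
  expect_true(dp$verdict$accepted)
  expect_gt(dp$verdict$decision_value, 0)
  # one signal-free replicate is rejected as a whole
  cm_bad <- failed_ip_counts()
  dp_bad <- suppressWarnings(discretize(cm_bad, qc_model = model))
  expect_false(dp_bad$verdict$accepted)
  expect_lt(dp_bad$verdict$decision_value, 0)
  # determinism of classification
  v1 <- qc_classify(model, dp$features)
  v2 <- qc_classify(model, dp$features)
  expect_identical(v1, v2)
  f_bad <- dp$features
  f_bad["min_snr"] <- NaN
  expect_error(qc_classify(model, f_bad), "min_snr")
})

test_that("features are robust to uniform depth scaling", {
  sim <- simulate_chip(sim_config(n_windows = 3000, n_chrom = 1, seed = 5200))
  cm <- sim$counts
  cm3 <- count_matrix(cm$grid, cm$counts * 3L, cm$roles)
  f1 <- discretize(cm)$features
  f3 <- discretize(cm3)$features
  expect_lt(abs(f1["target_fraction"] - f3["target_fraction"]), 0.02)
  expect_lt(abs(f1["min_snr"] / f3["min_snr"] - 1), 0.10)
})
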