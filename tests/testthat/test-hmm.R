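test_that("forward-backward matches exhaustive path enumeration", {
  for (case in 1:2) {
    set.seed(40 + case)
    r <- case                       # r = 1 with n = 8, r = 2 with n = 5
    n <- c(8L, 5L)[case]
    y <- matrix(stats::rpois(n * r, 3), ncol = r)
    params <- toy_hmm_params(r)
    bf <- enumerate_hmm(y, params)
    fb <- forward_backward(y, params)
    expect_lt(max(abs(fb$gamma - bf$posteriors)), 1e-10)
    expect_lt(abs(fb$loglik - bf$loglik), 1e-10)
    expect_lt(max(abs(fb$xi_sum - bf$xi)), 1e-10)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
  }
})

test_that("viterbi attains the brute-force optimal path log-probability", {
  for (case in 1:3) {
    set.seed(50 + case)
    y <- matrix(stats::rpois(8, c(2, 5, 9)[case]), ncol = 1)
    params <- toy_hmm_params(1L)
    bf <- enumerate_hmm(y, params)
    v <- viterbi(y, params)
    expect_equal(path_logprob(y, params, v), bf$best_logprob)
  }
})

test_that("degenerate chains behave as expected", {
  params <- toy_hmm_params(1L)
  # absorbing chain: identity transitions, start in state 1
  pa <- hmm_params(nu = c(1, 0, 0), Q = diag(3), pi = params$pi,
                   alpha = params$alpha, P = params$P)
  y <- matrix(c(0L, 3L, 10L, 1L), ncol = 1)
  fb <- forward_backward(y, pa)
  expect_equal(fb$gamma[, 1], rep(1, 4))
  expect_equal(viterbi(y, pa), rep(1L, 4))
  # identity transitions concentrated on state 3
  pc <- hmm_params(nu = c(0, 0, 1), Q = diag(3), pi = params$pi,
                   alpha = params$alpha, P = params$P)
  expect_equal(viterbi(y, pc), rep(3L, 4))
  # uninformative emissions: posteriors equal the chain marginals
  Pu <- matrix(rep(c(0.6, 0.4), each = 3), 3)
  pu <- hmm_params(nu = c(0.5, 0.3, 0.2),
                   Q = rbind(c(0.7, 0.2, 0.1), c(0.3, 0.5, 0.2),
                             c(0.25, 0.25, 0.5)),
                   pi = 0.1, alpha = 2, P = Pu)
  fbu <- forward_backward(y, pu)
  marg <- matrix(0, 4, 3)
  marg[1, ] <- pu$nu
  for (t in 2:4) marg[t, ] <- marg[t - 1, ] %*% pu$Q
  expect_lt(max(abs(fbu$gamma - marg)), 1e-12)
})

test_that("viterbi tie-breaks deterministically toward the lower state index", {
  # two states with identical emissions and a symmetric chain: every
  # path through {1, 2} ties; the decoder must pick state 1 throughout
  P <- rbind(c(0.6, 0.4), c(0.6, 0.4), c(0.1, 0.9))
  Q <- rbind(c(0.45, 0.45, 0.10), c(0.45, 0.45, 0.10), c(0.2, 0.2, 0.6))
  par <- hmm_params(nu = c(0.5, 0.5, 0), Q = Q, pi = 0, alpha = 1, P = P)
  y <- matrix(c(1L, 2L, 0L, 1L), ncol = 1)
  expect_equal(viterbi(y, par), rep(1L, 4))
})

test_that("chromosome blocks are independent chains restarted from nu", {
  set.seed(61)
  params <- toy_hmm_params(1L)
  y1 <- matrix(stats::rpois(4, 3), ncol = 1)
  y2 <- matrix(stats::rpois(3, 6), ncol = 1)
  whole <- forward_backward(rbind(y1, y2), params,
                            blocks = data.frame(from = c(1L, 5L), to = c(4L, 7L)))
  sep1 <- forward_backward(y1, params)
  sep2 <- forward_backward(y2, params)
  expect_equal(whole$loglik, sep1$loglik + sep2$loglik)
  expect_equal(whole$gamma, rbind(sep1$gamma, sep2$gamma))
  vit <- viterbi(rbind(y1, y2), params,
                 blocks = data.frame(from = c(1L, 5L), to = c(4L, 7L)))
  expect_equal(vit, c(viterbi(y1, params), viterbi(y2, params)))
})

test_that("baseline fit from controls recovers and pools correctly", {
  sim <- simulate_chip(sim_config(n_windows = 20000, n_chrom = 1, r = 1,
                                  pi = 0.25, alpha = 3, seed = 71))
  bl <- fit_baseline(sim$counts)
  expect_lt(abs(bl$pi - 0.25) / 0.25, 0.05)
  expect_lt(abs(bl$alpha - 3) / 3, 0.05)
  # single column: identical to a direct ZINB fit
  ctrl <- control_counts(sim$counts)
  direct <- fit_zinb(as.integer(ctrl[, 1]))
  expect_equal(bl$pi, direct$pi)
  expect_equal(bl$alpha, direct$alpha)
  # two control columns sharing the window intensity: pooling doubles
  # the depth but leaves the baseline (pi, alpha) intact
  flat <- simulate_chip(sim_config(n_windows = 20000, n_chrom = 1, r = 2,
                                   pi = 0.25, alpha = 3,
                                   state_means = c(4, 4, 4), seed = 72))
  cm2 <- count_matrix(flat$counts$grid,
                      cbind(chip_counts(flat$counts), control_counts(flat$counts)),
                      c("control", "control", "chip"))
  bl2 <- fit_baseline(cm2)
  expect_lt(abs(bl2$pi - 0.25) / 0.25, 0.05)
  expect_lt(abs(bl2$alpha - 3) / 3, 0.05)
  expect_error(fit_baseline(matrix(0L, 100, 1)), "degenerate")
})

test_that("EM log-likelihood trace is non-decreasing across random datasets", {
  for (i in 1:20) {
    set.seed(300 + i)
    y <- cbind(stats::rnbinom(300, size = 2, mu = sample(2:6, 1)),
               stats::rnbinom(300, size = 2, mu = sample(2:6, 1)))
    y[stats::runif(300) < 0.1, ] <- 0L
    fit <- suppressWarnings(baum_welch(y, pi = 0.1, alpha = 2, max_iter = 15))
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-6 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("iteration control and fixed-point behaviour of Baum-Welch", {
  sim <- simulate_chip(sim_config(n_windows = 5000, n_chrom = 1, seed = 81))
  y <- chip_counts(sim$counts)
  # tol = Inf: exactly one EM iteration, valid fit
  f1 <- baum_welch(y, pi = 0.1, alpha = 4, tol = Inf)
  expect_s3_class(f1, "hmm_fit")
  expect_equal(f1$n_iter, 1L)
  expect_true(all(f1$viterbi_path %in% 1:3))
  # initialization at the truth: first iteration barely moves
  means <- sim$config$state_means
  lam <- rbind(means, means) / sim$config$alpha   # r = 2, equal depths
  P <- t(apply(lam, 2, function(l) c(1, l) / (1 + sum(l))))
  truth <- hmm_params(nu = sim$config$nu, Q = sim$config$Q,
                      pi = sim$config$pi, alpha = sim$config$alpha, P = P)
  f2 <- baum_welch(y, pi = sim$config$pi, alpha = sim$config$alpha,
                   init = truth, max_iter = 2, tol = 0)
  tr <- f2$loglik_trace
  expect_lt(abs(tr[2] - tr[1]) / abs(tr[1]), 1e-3)
})

test_that("state roles are ranked by mean signal, invariant to label switching", {
  P <- rbind(c(1, 1, 4) / 6, c(1, 4, 20) / 25, c(1, 10, 40) / 51)
  par <- hmm_params(nu = rep(1 / 3, 3), Q = matrix(1 / 3, 3, 3),
                    pi = 0.1, alpha = 2, P = P)
  expect_equal(as.integer(identify_state_roles(par)), c(0L, 1L, 2L))
  # permute states: roles follow the permutation
  perm <- c(3L, 1L, 2L)
  par_p <- hmm_params(nu = rep(1 / 3, 3), Q = matrix(1 / 3, 3, 3),
                      pi = 0.1, alpha = 2, P = P[perm, ])
  expect_equal(as.integer(identify_state_roles(par_p)),
               as.integer(identify_state_roles(par))[perm])
  # ties warn and fall back to raw index order
  par_t <- hmm_params(nu = rep(1 / 3, 3), Q = matrix(1 / 3, 3, 3),
                      pi = 0.1, alpha = 2, P = P[c(1, 1, 3), ])
  expect_warning(identify_state_roles(par_t), "tied")
})

test_that("label switching at initialization does not change the role track", {
  sim <- simulate_chip(sim_config(n_windows = 3000, n_chrom = 1, seed = 91))
  y <- chip_counts(sim$counts)
  init <- chipstate:::init_hmm_params(y, 0.1, 4)
  perm <- c(2L, 3L, 1L)
  init_p <- hmm_params(init$nu[perm], init$Q[perm, perm], init$pi,
                       init$alpha, init$P[perm, ])
  f <- baum_welch(y, 0.1, 4, init = init, max_iter = 40)
  f_p <- baum_welch(y, 0.1, 4, init = init_p, max_iter = 40)
  expect_equal(f$state_order[f$viterbi_path],
               f_p$state_order[f_p$viterbi_path])
})

test_that("the conventional free-parameter count is 3r + 9", {
  for (r in 1:4) {
    np <- n_free_parameters(r)
    expect_equal(as.integer(np), 3L * r + 9L)
    b <- attr(np, "breakdown")
    expect_equal(unname(b["emission_table"] + b["transition_free"]),
                 as.integer(np))
  }
})

test_that("discretization recovers simulated states and stays quiet on null data", {
  sim <- simulate_chip(sim_config(n_windows = 5000, n_chrom = 2, seed = 101))
  dp <- discretize(sim$counts)
  acc <- mean(dp$state == sim$states[, 1] - 1L)
  expect_gte(acc, 0.95)
  expect_true(all(dp$confidence >= 0 & dp$confidence <= 1))
  # confidence is the posterior of the called state
  i <- which.max(dp$confidence)
  expect_equal(dp$confidence[i],
               max(dp$fit$posteriors[i, ]))
  # chip columns that are just control draws: targets essentially absent
  null_sim <- simulate_chip(sim_config(n_windows = 4000, n_chrom = 1,
                                       state_means = c(4, 4, 4),
                                       control_mean = 4, seed = 102))
  dp0 <- suppressWarnings(discretize(null_sim$counts))
  expect_lte(mean(dp0$state == 2), 0.01)
  # all-zero windows are never targets
  expect_false(any(target_windows(dp) & rowSums(sim$counts$counts) == 0))
})

test_that("discretization outputs round-trip to disk", {
  sim <- simulate_chip(sim_config(n_windows = 500, n_chrom = 2, seed = 111))
  dp <- discretize(sim$counts, max_iter = 20)
  prefix <- tempfile()
  files <- write_discretization(dp, prefix)
  expect_true(all(file.exists(files)))
  w <- utils::read.delim(files[1])
  expect_equal(nrow(w), 1000L)
  expect_equal(w$state, dp$state)
  ti <- target_intervals(dp)
  if (nrow(ti) > 0) {
    expect_true(all(ti$end > ti$start))
    # merged intervals cover exactly the target windows
    expect_equal(sum((ti$end - ti$start) / 300),
                 sum(target_windows(dp)))
  }
})
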