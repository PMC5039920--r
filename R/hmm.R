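#' Three-state HMM parameter set
#'
#' Parameters of the hidden Markov model used for discretization: an
#' initial state distribution, a 3x3 transition matrix and one
#' negative-multinomial emission probability vector per state. The
#' zero-inflation `pi` and shape `alpha` are shared by all states
#' (they describe the baseline distribution of reads over windows and
#' are fitted from the negative controls), while the probability
#' vectors `P[s, ] = (p0, p1, ..., pr)` are state-dependent and set the
#' expected read counts of each replicate in each state.
#'
#' @param nu initial state distribution, length 3, sums to 1.
#' @param Q 3x3 row-stochastic transition matrix.
#' @param pi shared zero-inflation probability.
#' @param alpha shared shape parameter.
#' @param P 3 x (r+1) matrix of per-state probability vectors, rows sum
#'   to 1.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(nu, Q, pi, alpha, P) {
  if (length(nu) != 3L || abs(sum(nu) - 1) > 1e-8 || any(nu < 0))
    stop("'nu' must be a length-3 probability vector")
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(3L, 3L)) || any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8))
    stop("'Q' must be a 3x3 row-stochastic matrix")
  P <- as.matrix(P)
  if (nrow(P) != 3L || ncol(P) < 2L)
    stop("'P' must be a 3 x (r+1) matrix")
  for (s in 1:3) check_zinm_params(pi, alpha, P[s, ])
  structure(list(nu = as.numeric(nu), Q = Q, pi = pi, alpha = alpha, P = P),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  r <- ncol(x$P) - 1L
  cat(sprintf("hmm_params: 3 states, %d replicate(s), pi=%.4f alpha=%.4f\n",
              r, x$pi, x$alpha))
  invisible(x)
}

#' Conventional free-parameter count of the discretization model
#'
#' Returns `3r + 9` for `r` ChIP replicates: the 3 x (r+1) table of
#' state-dependent emission probabilities plus the 6 free entries of
#' the row-stochastic transition matrix, with the baseline pair
#' (`pi`, `alpha`) pre-fitted from controls and the initial state
#' distribution counted with the transition structure. A stricter
#' simplex accounting (r free probabilities per state, 6 in Q, 2 in
#' nu, plus the baseline pair) is attached as attribute `breakdown`.
#'
#' @param r number of ChIP replicates.
#' @return integer `3r + 9`, with attribute `breakdown`.
#' @export
n_free_parameters <- function(r) {
  structure(3L * as.integer(r) + 9L,
            breakdown = c(emission_table = 3L * (r + 1L), transition_free = 6L,
                          simplex_free_emissions = 3L * r, nu_free = 2L,
                          baseline = 2L))
}

# Per-window emission log-probabilities, n x 3, using only chip columns.
emission_loglik <- function(y, params) {
  vapply(1:3, function(s) dzinm(y, params$pi, params$alpha, params$P[s, ], log = TRUE),
         numeric(nrow(y)))
}

block_ranges <- function(n, blocks = NULL) {
  if (is.null(blocks)) return(data.frame(from = 1L, to = n))
  stopifnot(all(blocks$from >= 1), all(blocks$to <= n))
  blocks[, c("from", "to")]
}

#' Forward-backward algorithm with scaled recursions
#'
#' Computes posterior state probabilities, expected transition counts
#' and the observation log-likelihood for the three-state model.
#' Chromosomes are treated as independent chains restarted from the
#' initial distribution, with their log-likelihoods summed. Recursions
#' are normalized at every position so no underflow can occur.
#'
#' @param y integer matrix of chip counts (n windows x r replicates).
#' @param params an [hmm_params()] object.
#' @param blocks optional data.frame with columns `from`, `to` giving
#'   per-chromosome row ranges (defaults to a single chain).
#' @return list with `gamma` (n x 3 posteriors), `xi_sum` (3 x 3
#'   expected transition counts), `first_gamma` (posteriors at chain
#'   starts), `loglik`.
#' @export
forward_backward <- function(y, params, blocks = NULL) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- nrow(y)
  E <- emission_loglik(y, params)
  br <- block_ranges(n, blocks)
  gamma <- matrix(0, n, 3)
  xi_sum <- matrix(0, 3, 3)
  first_gamma <- matrix(0, nrow(br), 3)
  loglik <- 0
  Q <- params$Q
  for (b in seq_len(nrow(br))) {
    idx <- br$from[b]:br$to[b]
    Eb <- E[idx, , drop = FALSE]
    Tn <- length(idx)
    m <- apply(Eb, 1, max)
    B <- exp(Eb - m)
    a <- matrix(0, Tn, 3)
    cvec <- numeric(Tn)
    v <- params$nu * B[1, ]
    cvec[1] <- sum(v)
    a[1, ] <- v / cvec[1]
    if (Tn > 1) {
      for (t in 2:Tn) {
        v <- (a[t - 1, ] %*% Q) * B[t, ]
        cvec[t] <- sum(v)
        a[t, ] <- v / cvec[t]
      }
    }
    bt <- matrix(0, Tn, 3)
    bt[Tn, ] <- 1
    if (Tn > 1) {
      for (t in (Tn - 1):1) {
        bt[t, ] <- Q %*% (B[t + 1, ] * bt[t + 1, ]) / cvec[t + 1]
      }
    }
    g <- a * bt
    g <- g / rowSums(g)
    gamma[idx, ] <- g
    first_gamma[b, ] <- g[1, ]
    if (Tn > 1) {
      V <- B[2:Tn, , drop = FALSE] * bt[2:Tn, , drop = FALSE] /
        cvec[2:Tn]
      xi_sum <- xi_sum + Q * crossprod(a[1:(Tn - 1), , drop = FALSE], V)
    }
    loglik <- loglik + sum(log(cvec)) + sum(m)
  }
  list(gamma = gamma, xi_sum = xi_sum, first_gamma = first_gamma,
       loglik = loglik)
}

#' Viterbi decoding
#'
#' Most probable state path given parameters, decoded independently
#' per chromosome block. Ties are broken toward the lower state index
#' at every maximization, which makes the returned path deterministic.
#'
#' @inheritParams forward_backward
#' @return integer vector of states in `{1, 2, 3}` (raw state index).
#' @export
viterbi <- function(y, params, blocks = NULL) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- nrow(y)
  E <- emission_loglik(y, params)
  br <- block_ranges(n, blocks)
  logQ <- log(params$Q)
  lognu <- log(params$nu)
  path <- integer(n)
  for (b in seq_len(nrow(br))) {
    idx <- br$from[b]:br$to[b]
    Eb <- E[idx, , drop = FALSE]
    Tn <- length(idx)
    delta <- lognu + Eb[1, ]
    psi <- matrix(0L, Tn, 3)
    if (Tn > 1) {
      for (t in 2:Tn) {
        cand <- delta + logQ            # cand[s, s'] = delta[s] + logQ[s, s']
        best <- apply(cand, 2, which.max)  # ties -> lowest index
        delta <- cand[cbind(best, 1:3)] + Eb[t, ]
        psi[t, ] <- best
      }
    }
    p <- integer(Tn)
    p[Tn] <- which.max(delta)
    if (Tn > 1) for (t in (Tn - 1):1) p[t] <- psi[t + 1, p[t + 1]]
    path[idx] <- p
  }
  path
}

#' Baseline fit from negative controls
#'
#' Pools the control columns (summed across controls per window) and
#' fits the zero-inflated negative binomial; the resulting
#' zero-inflation and shape are held fixed through all Baum-Welch
#' iterations, since they describe the baseline behaviour of genomic
#' windows rather than the abundance of the chromatin feature.
#'
#' @param controls integer matrix of control counts (n x c) or a
#'   `count_matrix` (its control columns are used).
#' @return list with `pi` and `alpha` plus the full `zinb_fit`.
#' @export
fit_baseline <- function(controls) {
  if (inherits(controls, "count_matrix")) controls <- control_counts(controls)
  if (is.null(dim(controls))) controls <- matrix(controls, ncol = 1)
  if (ncol(controls) < 1L) stop("need at least one control column")
  pooled <- as.integer(rowSums(controls))
  if (all(pooled == 0)) stop("degenerate controls: all counts are zero")
  fit <- fit_zinb(pooled)
  list(pi = fit$pi, alpha = fit$alpha, fit = fit)
}

# Deterministic quantile-based seeding: windows are split by total chip
# count into bottom 50% / next 40% / top 10% to seed the three emission
# states; nu uniform; Q sticky.
init_hmm_params <- function(y, pi, alpha) {
  tot <- rowSums(y)
  qs <- stats::quantile(tot, c(0.5, 0.9), type = 1)
  groups <- 1L + (tot > qs[1]) + (tot > qs[2])
  P <- matrix(0, 3, ncol(y) + 1L)
  for (s in 1:3) {
    w <- as.numeric(groups == s)
    if (sum(w) == 0) w <- rep(1 / length(tot), length(tot))
    P[s, ] <- fit_nm_probs(y, w, pi, alpha)
  }
  Q <- matrix(0.025, 3, 3); diag(Q) <- 0.95
  hmm_params(nu = rep(1 / 3, 3), Q = Q, pi = pi, alpha = alpha, P = P)
}

#' Baum-Welch estimation of the discretization HMM
#'
#' Expectation-maximization for the three-state model: the E-step runs
#' the scaled forward-backward recursions, the M-step re-estimates the
#' initial distribution and transition matrix from expected counts and
#' each state's emission probability vector by the weighted
#' negative-multinomial update ([fit_nm_probs()]) with posterior
#' responsibilities as weights. The shared `(pi, alpha)` pair stays
#' pinned at the control fit. The log-likelihood trace is
#' non-decreasing up to numerical slack.
#'
#' @param y chip count matrix (n x r) or a `count_matrix` (chip
#'   columns and chromosome blocks are extracted).
#' @param pi,alpha baseline parameters from [fit_baseline()].
#' @param init optional [hmm_params()] to start from; default is a
#'   deterministic quantile-based seeding.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param blocks optional block ranges (ignored when `y` is a
#'   `count_matrix`).
#' @return an object of class `hmm_fit`: list with `params`,
#'   `posteriors`, `viterbi_path` (raw states), `loglik_trace`,
#'   `n_iter`, `converged`, `state_order` (see
#'   [identify_state_roles()]).
#' @export
baum_welch <- function(y, pi, alpha, init = NULL, max_iter = 100L,
                       tol = 1e-6, blocks = NULL) {
  if (inherits(y, "count_matrix")) {
    blocks <- y$grid$blocks
    y <- chip_counts(y)
  }
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (ncol(y) < 1L) stop("need at least one chip column")
  params <- if (is.null(init)) init_hmm_params(y, pi, alpha) else init
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(y, params, blocks)
    trace <- c(trace, fb$loglik)
    if (iter > 1L &&
        abs(fb$loglik - trace[iter - 1L]) <= tol * (abs(trace[iter - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
    # M-step
    nu <- colSums(fb$first_gamma)
    nu <- nu / sum(nu)
    Q <- fb$xi_sum
    rs <- rowSums(Q)
    for (s in 1:3) {
      if (rs[s] > 0) Q[s, ] <- Q[s, ] / rs[s] else Q[s, ] <- params$Q[s, ]
    }
    P <- params$P
    for (s in 1:3) {
      resp <- fb$gamma[, s]
      if (sum(resp) < 1e-8) {
        warning("state ", s, " collapsed (total responsibility ~ 0); ",
                "emission update skipped this iteration")
        next
      }
      P[s, ] <- fit_nm_probs(y, resp, pi, alpha)
    }
    params <- hmm_params(nu, Q, pi, alpha, P)
    n_iter <- iter
  }
  if (!converged) {  # refresh posteriors so they match the returned params
    fb <- forward_backward(y, params, blocks)
    trace <- c(trace, fb$loglik)
  }
  structure(list(params = params, posteriors = fb$gamma,
                 viterbi_path = viterbi(y, params, blocks),
                 loglik_trace = trace, loglik = fb$loglik,
                 n_iter = n_iter, converged = converged,
                 state_order = identify_state_roles(params)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: loglik=%.2f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Identify low / medium / high state roles
#'
#' Ranks the three states by the expected total chip signal per window
#' they imply (`alpha * sum_j p_j / p0`, summed over replicates),
#' ascending, and labels them low (0), medium (1) and high (2). The
#' 'high' state windows are the targets of the chromatin feature.
#' Ties are resolved by raw state index with a warning.
#'
#' @param params an [hmm_params()] object.
#' @return integer vector of length 3 giving each raw state's role
#'   (0 = low, 1 = medium, 2 = high), with attribute `state_means`.
#' @export
identify_state_roles <- function(params) {
  means <- state_mean_rates(params)
  tot <- rowSums(means)
  if (anyDuplicated(signif(tot, 12)))
    warning("tied state mean signals; roles assigned by raw state index")
  role <- integer(3)
  role[order(tot)] <- 0:2
  structure(role, state_means = means)
}

# Per-state, per-replicate mean counts implied by the emission
# parameters: alpha * p_j / p0.
state_mean_rates <- function(params) {
  t(apply(params$P, 1, function(p) params$alpha * p[-1L] / p[1L]))
}

#' Discretize a replicated ChIP-seq count matrix
#'
#' Full discretization: fit the baseline zero-inflation and shape from
#' the pooled controls, run Baum-Welch on the chip columns, decode the
#' most likely segmentation with Viterbi, and map raw states to
#' low/medium/high roles. Windows that are zero in every profile stay
#' in the chain (the zero-inflation component absorbs them) but are
#' never reported as targets. If a QC model is supplied (and there are
#' at least two replicates) the five-feature quality-control verdict
#' is attached.
#'
#' @param x a `count_matrix` with at least one control and one chip
#'   column.
#' @param max_iter,tol Baum-Welch controls.
#' @param qc_model optional `qc_model` object from [train_qc()].
#' @return an object of class `discretized_profile`: list with
#'   `windows` (chrom/start/end), `state` (0 = low, 1 = medium,
#'   2 = high), `confidence` (posterior probability of the called
#'   state), `fit` (the `hmm_fit`), `baseline`, `features`
#'   (if computable) and `verdict` (if a QC model was given).
#' @export
discretize <- function(x, max_iter = 100L, tol = 1e-6, qc_model = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (sum(x$roles == "control") < 1L || sum(x$roles == "chip") < 1L)
    stop("discretization needs at least one control and one chip profile")
  baseline <- fit_baseline(x)
  fit <- baum_welch(x, pi = baseline$pi, alpha = baseline$alpha,
                    max_iter = max_iter, tol = tol)
  role <- fit$state_order[fit$viterbi_path]
  confidence <- fit$posteriors[cbind(seq_along(role), fit$viterbi_path)]
  all_zero <- rowSums(x$counts) == 0
  out <- structure(list(windows = x$grid$windows, state = role,
                        confidence = confidence, all_zero = all_zero,
                        fit = fit, baseline = baseline,
                        features = NULL, verdict = NULL),
                   class = "discretized_profile")
  out$features <- qc_features(fit, x)
  if (!is.null(qc_model)) out$verdict <- qc_classify(qc_model, out$features)
  out
}

#' @export
print.discretized_profile <- function(x, ...) {
  n <- length(x$state)
  cat(sprintf("discretized_profile: %d windows; low/medium/high = %d/%d/%d\n",
              n, sum(x$state == 0), sum(x$state == 1), sum(x$state == 2)))
  if (!is.null(x$verdict))
    cat(sprintf("QC: %s (decision value %.3f)\n",
                if (x$verdict$accepted) "accepted" else "REJECTED",
                x$verdict$decision_value))
  invisible(x)
}

#' Target windows and merged target intervals
#'
#' Targets are the windows called 'high', excluding windows with zero
#' counts in every profile. `target_intervals` merges maximal runs of
#' adjacent target windows into BED-style intervals.
#'
#' @param x a `discretized_profile`.
#' @return `target_windows`: logical vector over windows.
#'   `target_intervals`: data.frame chrom/start/end.
#' @export
target_windows <- function(x) {
  stopifnot(inherits(x, "discretized_profile"))
  x$state == 2L & !x$all_zero
}

#' @rdname target_windows
#' @export
target_intervals <- function(x) {
  tw <- target_windows(x)
  w <- x$windows
  keep <- which(tw)
  if (length(keep) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  # break runs at chromosome changes or non-adjacent windows
  new_run <- c(TRUE, diff(keep) != 1L |
                 w$chrom[keep[-1]] != w$chrom[keep[-length(keep)]])
  run_id <- cumsum(new_run)
  data.frame(
    chrom = tapply(w$chrom[keep], run_id, `[`, 1L),
    start = as.integer(tapply(w$start[keep], run_id, min)),
    end = as.integer(tapply(w$end[keep], run_id, max)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write discretization outputs
#'
#' Writes `<prefix>_windows.tsv` (chrom, start, end, state,
#' confidence), `<prefix>_targets.bed` (merged target intervals) and
#' `<prefix>_params.tsv` (key-value parameter report).
#'
#' @param x a `discretized_profile`.
#' @param prefix output path prefix.
#' @return invisibly, the vector of files written.
#' @export
write_discretization <- function(x, prefix) {
  stopifnot(inherits(x, "discretized_profile"))
  f1 <- paste0(prefix, "_windows.tsv")
  df <- cbind(x$windows, state = x$state,
              confidence = signif(x$confidence, 6))
  utils::write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- paste0(prefix, "_targets.bed")
  ti <- target_intervals(x)
  utils::write.table(ti, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  f3 <- paste0(prefix, "_params.tsv")
  p <- x$fit$params
  kv <- c(pi = p$pi, alpha = p$alpha,
          stats::setNames(as.vector(t(p$Q)),
                          paste0("Q", rep(1:3, each = 3), rep(1:3, 3))),
          stats::setNames(p$nu, paste0("nu", 1:3)),
          stats::setNames(as.vector(t(p$P)),
                          paste0("p", rep(1:3, each = ncol(p$P)), "_",
                                 rep(seq_len(ncol(p$P)) - 1L, 3))),
          loglik = x$fit$loglik, n_iter = x$fit$n_iter)
  if (!is.null(x$features))
    kv <- c(kv, stats::setNames(as.numeric(x$features), paste0("qc_", names(x$features))))
  if (!is.null(x$verdict))
    kv <- c(kv, qc_accepted = as.numeric(x$verdict$accepted),
            qc_decision_value = x$verdict$decision_value)
  utils::write.table(data.frame(key = names(kv), value = unname(kv)),
                     f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
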