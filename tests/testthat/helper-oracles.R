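# Brute-force oracles, independent of the package's recursions: they
# enumerate all 3^n state paths directly from the model definition.

path_logprob <- function(y, params, path) {
  E <- sapply(1:3, function(s)
    dzinm(y, params$pi, params$alpha, params$P[s, ], log = TRUE))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  v <- log(params$nu[path[1]]) + E[1, path[1]]
  if (length(path) > 1) {
    for (t in 2:length(path))
      v <- v + log(params$Q[path[t - 1], path[t]]) + E[t, path[t]]
  }
  v
}

enumerate_hmm <- function(y, params) {
  n <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(p) path_logprob(y, params, p))
  m <- max(lp)
  loglik <- m + log(sum(exp(lp - m)))
  w <- exp(lp - m); w <- w / sum(w)
  post <- sapply(1:3, function(s)
    sapply(1:n, function(t) sum(w[paths[, t] == s])))
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  xi <- matrix(0, 3, 3)
  if (n > 1) {
    for (t in 2:n) for (s in 1:3) for (sp in 1:3)
      xi[s, sp] <- xi[s, sp] + sum(w[paths[, t - 1] == s & paths[, t] == sp])
  }
  list(posteriors = post, loglik = loglik, xi = xi,
       best_path = paths[which.max(lp), ], best_logprob = m)
}

toy_hmm_params <- function(r = 1L, pi = 0.2, alpha = 1.5) {
  P <- switch(r,
    rbind(c(0.70, 0.30), c(0.40, 0.60), c(0.15, 0.85)),
    rbind(c(0.60, 0.25, 0.15), c(0.40, 0.35, 0.25), c(0.15, 0.45, 0.40)))
  hmm_params(nu = c(0.5, 0.3, 0.2),
             Q = rbind(c(0.7, 0.2, 0.1), c(0.3, 0.5, 0.2), c(0.25, 0.25, 0.5)),
             pi = pi, alpha = alpha, P = P)
}

# Negative ZINB log-likelihood in unconstrained coordinates, for the
# generic-optimizer oracle.
zinb_nll <- function(par, x) {
  -sum(dzinb(x, stats::plogis(par[1]), exp(par[2]), stats::plogis(par[3]),
             log = TRUE))
}
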