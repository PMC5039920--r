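#' Zero-inflated negative binomial probability mass function
#'
#' Density of the mixture of a point mass at zero (weight `pi`) and a
#' negative binomial distribution with shape `alpha` and success
#' probability `p` (so the complementary mass parameter is `p0 = 1 - p`
#' and the negative binomial mean is `alpha * p / p0`). The zero class
#' absorbs genomic windows where no read can ever map; the negative
#' binomial models the overdispersed read counts of mappable windows.
#'
#' @param x vector of non-negative integer counts.
#' @param pi zero-inflation probability in `[0, 1]`.
#' @param alpha shape parameter, `> 0`.
#' @param p success-probability-like parameter in `(0, 1)`.
#' @param log logical; return log-probabilities?
#' @return numeric vector of (log-)probabilities, same length as `x`.
#' @examples
#' sum(dzinb(0:200, pi = 0.3, alpha = 2, p = 0.5)) # ~1
#' @export
dzinb <- function(x, pi, alpha, p, log = FALSE) {
  check_zinb_params(pi, alpha, p)
  if (any(x < 0) || any(x != floor(x))) stop("'x' must contain non-negative integers")
  p0 <- 1 - p
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- log(pi + (1 - pi) * p0^alpha)
  if (any(!zero)) {
    k <- x[!zero]
    out[!zero] <- log1p(-pi) + lgamma(alpha + k) - lgamma(alpha) - lgamma(k + 1) +
      alpha * log(p0) + k * log(p)
  }
  if (log) out else exp(out)
}

#' Zero-inflated negative multinomial probability mass function
#'
#' Joint density of `r` correlated replicate counts per window. With
#' probability `pi` the window is structurally zero in every replicate;
#' otherwise counts follow a negative multinomial, the multivariate
#' extension of the negative binomial through its Gamma-Poisson
#' construction (one Gamma-distributed window intensity shared by all
#' replicates). The probability vector `prob = (p0, p1, ..., pr)` sums
#' to one; `p0` is the complementary mass and `p1..pr` set the mean
#' depth of each replicate.
#'
#' @param y non-negative integer matrix (`n` windows by `r` replicates)
#'   or a single length-`r` vector.
#' @param pi zero-inflation probability.
#' @param alpha shape parameter, `> 0`.
#' @param prob probability vector `(p0, p1, ..., pr)` summing to 1.
#' @param log logical; return log-probabilities?
#' @return numeric vector of length `n`.
#' @examples
#' dzinm(c(0, 0), pi = 0, alpha = 1, prob = c(0.25, 0.5, 0.25)) # 0.25
#' @export
dzinm <- function(y, pi, alpha, prob, log = FALSE) {
  check_zinm_params(pi, alpha, prob)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (ncol(y) != length(prob) - 1L)
    stop("'y' must have ", length(prob) - 1L, " columns to match 'prob'")
  if (any(y < 0) || any(y != floor(y))) stop("'y' must contain non-negative integers")
  p0 <- prob[1L]
  pj <- prob[-1L]
  rs <- rowSums(y)
  out <- numeric(nrow(y))
  zero <- rs == 0
  out[zero] <- log(pi + (1 - pi) * p0^alpha)
  if (any(!zero)) {
    yk <- y[!zero, , drop = FALSE]
    out[!zero] <- log1p(-pi) + lgamma(alpha + rs[!zero]) - lgamma(alpha) -
      rowSums(lgamma(yk + 1)) + alpha * log(p0) + drop(yk %*% log(pj))
  }
  if (log) out else exp(out)
}

check_zinb_params <- function(pi, alpha, p) {
  if (length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1)
    stop("'pi' must be a single value in [0, 1]")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive value")
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single value in (0, 1)")
  invisible(TRUE)
}

check_zinm_params <- function(pi, alpha, prob) {
  if (length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1)
    stop("'pi' must be a single value in [0, 1]")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive value")
  if (length(prob) < 2L || any(is.na(prob)) || any(prob <= 0))
    stop("'prob' must have length >= 2 with all entries > 0")
  if (abs(sum(prob) - 1) > 1e-8)
    stop("'prob' must sum to 1 (got ", format(sum(prob)), ")")
  invisible(TRUE)
}

# Full-data ZINB log-likelihood from the zero count and the table of
# positive counts (vals, freq).
zinb_loglik_tab <- function(n0, vals, freq, pi, alpha, p0) {
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(pi + (1 - pi) * p0^alpha)
  if (length(vals)) {
    ll <- ll + sum(freq * (log1p(-pi) + lgamma(alpha + vals) - lgamma(alpha) -
      lgamma(vals + 1) + alpha * log(p0) + vals * log(1 - p0)))
  }
  ll
}

# Profile score in alpha for a weighted negative binomial fit where the
# odds parameter is profiled out: p0 = alpha / (alpha + mu) with mu the
# weighted mean. Zeros contribute only through the total weight and mu.
nb_alpha_score <- function(alpha, vals, wfreq, W, mu) {
  sum(wfreq * (digamma(alpha + vals) - digamma(alpha))) +
    W * log(alpha / (alpha + mu))
}

# Solve nb_alpha_score(alpha) = 0 by damped Newton with a bisection
# fallback on a sign-changing bracket. The score is decreasing in alpha
# for overdispersed data; for data at or under Poisson dispersion the
# score stays positive and alpha escapes to the upper cap (quasi-Poisson
# regime), which is reported as such.
solve_nb_alpha <- function(vals, wfreq, W, mu, lower = 1e-4, upper = 1e6) {
  f <- function(a) nb_alpha_score(a, vals, wfreq, W, mu)
  flo <- f(lower)
  fhi <- f(upper)
  if (flo <= 0) return(lower)
  if (fhi >= 0) return(upper)   # no finite root: quasi-Poisson limit
  lo <- lower; hi <- upper
  a <- max(min(mu^2 / max(stats::weighted.mean((vals - mu)^2, wfreq) - mu, 1e-8), hi), lo)
  for (iter in 1:100) {
    fa <- f(a)
    if (abs(fa) < 1e-10) break
    if (fa > 0) lo <- a else hi <- a
    fprime <- sum(wfreq * (trigamma(a + vals) - trigamma(a))) +
      W * (1 / a - 1 / (a + mu))
    step <- if (is.finite(fprime) && fprime < 0) -fa / fprime else NA_real_
    a_new <- if (!is.na(step)) a + step else NA_real_
    if (is.na(a_new) || a_new <= lo || a_new >= hi) a_new <- (lo + hi) / 2
    if (abs(a_new - a) < 1e-12 * max(1, a)) { a <- a_new; break }
    a <- a_new
  }
  a
}

#' Maximum-likelihood fit of the zero-inflated negative binomial
#'
#' Fits `(pi, alpha, p)` to a vector of window counts by an
#' expectation-maximization scheme over the latent zero-class
#' indicator, with the shape parameter updated at each M-step by a
#' damped Newton iteration (bisection-safeguarded) on its profile score
#' equation. Initial values come from method-of-moments estimates, with
#' the zero-inflation started at the excess-zero fraction relative to
#' the moment negative binomial. Boundary fits (`pi = 0`) are valid
#' outputs.
#'
#' @param x vector of non-negative integer counts, length >= 10, not
#'   all equal.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return an object of class `zinb_fit`: a list with elements `pi`,
#'   `alpha`, `p`, `loglik`, `n_iter`, `converged`, and `grad` (the
#'   projected score at the returned parameters).
#' @examples
#' set.seed(1)
#' x <- stats::rnbinom(500, size = 2, prob = 0.3)
#' x[stats::runif(500) < 0.2] <- 0
#' fit_zinb(x)
#' @export
fit_zinb <- function(x, tol = 1e-8, max_iter = 200L) {
  if (length(x) < 10L) stop("need at least 10 observations")
  if (any(x < 0) || any(x != floor(x))) stop("'x' must contain non-negative integers")
  if (all(x == x[1L])) stop("degenerate input: all counts equal")
  n <- length(x)
  n0 <- sum(x == 0)
  tab <- table(x[x > 0])
  vals <- as.numeric(names(tab))
  freq <- as.numeric(tab)

  # moment initialization
  m <- mean(x); v <- stats::var(x)
  alpha <- if (v > m * 1.0001) m^2 / (v - m) else 100
  alpha <- min(max(alpha, 1e-3), 1e5)
  p0 <- alpha / (alpha + m)
  piz <- max(0, min(0.95, (n0 / n - p0^alpha) / (1 - p0^alpha)))

  # short EM warm start over the latent zero-class indicator
  ll_old <- -Inf
  for (iter in 1:25) {
    A <- p0^alpha
    w <- if (piz > 0) piz / (piz + (1 - piz) * A) else 0
    piz <- n0 * w / n
    w_zero <- n0 * (1 - w)           # aggregate NB weight carried by zeros
    W <- w_zero + sum(freq)
    mu <- sum(freq * vals) / W
    alpha <- solve_nb_alpha(vals, freq, W, mu)
    p0 <- alpha / (alpha + mu)
    ll <- zinb_loglik_tab(n0, vals, freq, piz, alpha, p0)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-6 * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
  }
  # damped Newton-Raphson on the full score to machine-precision optimum
  nr <- zinb_newton(n0, vals, freq, n, piz, alpha, p0, tol = tol,
                    max_iter = max_iter)
  grad <- zinb_score(n0, vals, freq, n, nr$pi, nr$alpha, nr$p0)
  structure(list(pi = nr$pi, alpha = nr$alpha, p = 1 - nr$p0,
                 loglik = nr$loglik, n_iter = nr$n_iter,
                 converged = nr$converged, grad = grad),
            class = "zinb_fit")
}

# Analytic Hessian of the ZINB log-likelihood in (pi, alpha, p0).
zinb_hessian <- function(n0, vals, freq, n, piz, alpha, p0) {
  A <- p0^alpha
  lp <- log(p0)
  Z <- piz + (1 - piz) * A
  npos <- n - n0
  Sk <- sum(freq * vals)
  Zpi <- 1 - A
  Za <- (1 - piz) * A * lp
  Zp <- (1 - piz) * alpha * A / p0
  H <- matrix(0, 3, 3)
  H[1, 1] <- -n0 * Zpi^2 / Z^2 - npos / (1 - piz)^2
  H[1, 2] <- H[2, 1] <- n0 * ((-A * lp) * Z - Zpi * Za) / Z^2
  H[1, 3] <- H[3, 1] <- n0 * ((-alpha * A / p0) * Z - Zpi * Zp) / Z^2
  Zaa <- (1 - piz) * A * lp^2
  H[2, 2] <- n0 * (Zaa * Z - Za^2) / Z^2 +
    sum(freq * (trigamma(alpha + vals) - trigamma(alpha)))
  Zap <- (1 - piz) * (A / p0) * (1 + alpha * lp)
  H[2, 3] <- H[3, 2] <- n0 * (Zap * Z - Za * Zp) / Z^2 + npos / p0
  Zpp <- (1 - piz) * alpha * (alpha - 1) * A / p0^2
  H[3, 3] <- n0 * (Zpp * Z - Zp^2) / Z^2 - npos * alpha / p0^2 -
    Sk / (1 - p0)^2
  H
}

# Damped Newton-Raphson ascent of the ZINB log-likelihood with box
# constraints; drops the pi coordinate at the pi = 0 boundary when the
# score points outward, and backtracks on non-improving steps.
zinb_newton <- function(n0, vals, freq, n, piz, alpha, p0,
                        tol = 1e-8, max_iter = 200L) {
  theta <- c(piz, alpha, p0)
  ll <- zinb_loglik_tab(n0, vals, freq, theta[1], theta[2], theta[3])
  converged <- FALSE
  iter <- 0L
  gtol <- 1e-6 * max(1, n)   # gradient sup-norm tolerance, per observation
  for (iter in seq_len(max_iter)) {
    g_full <- zinb_score(n0, vals, freq, n, theta[1], theta[2], theta[3])
    at_zero <- theta[1] <= 1e-12 && g_full[1] <= 0
    active <- if (at_zero) 2:3 else 1:3
    g <- g_full[active]
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    H <- zinb_hessian(n0, vals, freq, n, theta[1], theta[2], theta[3])
    step <- tryCatch(-solve(H[active, active, drop = FALSE], g),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * g) <= 0)
      step <- g / max(abs(g))          # gradient fallback, unit sup-norm
    improved <- FALSE
    for (h in 0:30) {
      cand <- theta
      cand[active] <- theta[active] + step / 2^h
      cand[1] <- min(max(cand[1], 0), 1 - 1e-12)
      cand[2] <- max(cand[2], 1e-8)
      cand[3] <- min(max(cand[3], 1e-12), 1 - 1e-12)
      ll_new <- zinb_loglik_tab(n0, vals, freq, cand[1], cand[2], cand[3])
      if (is.finite(ll_new) && ll_new >= ll) {
        improved <- ll_new > ll
        delta <- ll_new - ll
        theta <- cand
        ll <- ll_new
        break
      }
    }
    if (!improved || delta < tol * (abs(ll) + 1e-12)) {
      g_full <- zinb_score(n0, vals, freq, n, theta[1], theta[2], theta[3])
      at_zero <- theta[1] <= 1e-12 && g_full[1] <= 0
      active <- if (at_zero) 2:3 else 1:3
      converged <- max(abs(g_full[active])) < gtol ||
        (improved && delta < tol * (abs(ll) + 1e-12))
      break
    }
  }
  list(pi = theta[1], alpha = theta[2], p0 = theta[3], loglik = ll,
       n_iter = iter, converged = converged)
}

# Projected score of the full ZINB log-likelihood; the pi component is
# projected at the pi = 0 boundary so that boundary optima score zero.
zinb_score <- function(n0, vals, freq, n, piz, alpha, p0) {
  A <- p0^alpha
  Z <- piz + (1 - piz) * A
  npos <- n - n0
  g_pi <- n0 * (1 - A) / Z - npos / (1 - piz)
  if (piz <= 0 && g_pi < 0) g_pi <- 0
  if (piz >= 1 && g_pi > 0) g_pi <- 0
  g_alpha <- n0 * (1 - piz) * A * log(p0) / Z +
    sum(freq * (digamma(alpha + vals) - digamma(alpha))) + npos * log(p0)
  g_p0 <- n0 * (1 - piz) * alpha * p0^(alpha - 1) / Z +
    npos * alpha / p0 - sum(freq * vals) / (1 - p0)
  c(pi = g_pi, alpha = g_alpha, p0 = g_p0)
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("ZINB fit: pi=%.4f alpha=%.4f p=%.4f  loglik=%.4f (%d iter%s)\n",
              x$pi, x$alpha, x$p, x$loglik, x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Reference Poisson and negative binomial fits
#'
#' Maximum-likelihood Poisson (closed form: rate = mean) and negative
#' binomial fits of a count vector, for comparison against the
#' zero-inflated fit. Since the three families are nested, the
#' log-likelihoods are ordered Poisson <= NB <= ZINB at their
#' respective maxima.
#'
#' @inheritParams fit_zinb
#' @return list with elements `poisson` (rate, loglik) and `nb`
#'   (alpha, p, loglik).
#' @export
reference_count_fits <- function(x) {
  if (any(x < 0) || any(x != floor(x))) stop("'x' must contain non-negative integers")
  if (all(x == x[1L])) stop("degenerate input: all counts equal")
  lambda <- mean(x)
  ll_pois <- sum(stats::dpois(x, lambda, log = TRUE))
  n0 <- sum(x == 0)
  tab <- table(x[x > 0])
  vals <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  W <- length(x)
  mu <- mean(x)
  alpha <- solve_nb_alpha(vals, freq, W, mu)
  p0 <- alpha / (alpha + mu)
  ll_nb <- zinb_loglik_tab(n0, vals, freq, 0, alpha, p0)
  list(poisson = list(rate = lambda, loglik = ll_pois),
       nb = list(alpha = alpha, p = 1 - p0, loglik = ll_nb))
}

#' Weighted negative-multinomial probability update
#'
#' Maximizes the weighted zero-inflated negative multinomial
#' log-likelihood over the probability simplex `(p0, p1, ..., pr)` with
#' the zero-inflation `pi` and shape `alpha` held fixed. This is the
#' per-state emission update of the Baum-Welch M-step, where the
#' weights are posterior state responsibilities. The replicate
#' probabilities are proportional to the weighted column sums given
#' `p0`, so the problem reduces to a one-dimensional root-finding on
#' the profile score of `p0`, solved by bracketed Newton iteration.
#'
#' @param y non-negative integer matrix, `n` windows by `r` replicates.
#' @param weights per-window weights in `[0, 1]`, length `n`.
#' @param pi fixed zero-inflation probability.
#' @param alpha fixed shape parameter.
#' @return probability vector `(p0, p1, ..., pr)` summing to 1.
#' @export
fit_nm_probs <- function(y, weights, pi, alpha) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- nrow(y); r <- ncol(y)
  if (length(weights) != n) stop("'weights' must have one entry per row of 'y'")
  if (any(weights < 0)) stop("'weights' must be non-negative")
  if (sum(weights) <= 0) stop("empty state: all weights are zero")
  rs <- rowSums(y)
  zero <- rs == 0
  W0 <- sum(weights[zero])
  Wp <- sum(weights[!zero])
  s <- colSums(y * weights)
  S <- sum(s)
  if (S <= 0) {
    warning("state carries only zero observations; returning near-degenerate probabilities")
    eps <- 1e-8
    return(c(1 - r * eps, rep(eps, r)))
  }
  p0 <- solve_nm_p0(W0, Wp, S, pi, alpha)
  c(p0, (1 - p0) * s / S)
}

# Profile score for p0:
#   d/dp0 [ W0 log(pi + (1-pi) p0^alpha) + Wp alpha log(p0) + S log(1-p0) ]
solve_nm_p0 <- function(W0, Wp, S, pi, alpha, tol = 1e-12) {
  f <- function(p0) {
    Z <- pi + (1 - pi) * p0^alpha
    W0 * (1 - pi) * alpha * p0^(alpha - 1) / Z + Wp * alpha / p0 - S / (1 - p0)
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  # closed forms when the zero-class term does not couple p0
  if (W0 == 0) return(Wp * alpha / (Wp * alpha + S))
  if (pi == 1) return(Wp * alpha / (Wp * alpha + S))
  if (pi == 0) return((W0 + Wp) * alpha / ((W0 + Wp) * alpha + S))
  p0 <- (W0 + Wp) * alpha / ((W0 + Wp) * alpha + S)  # pi = 0 solution as start
  p0 <- min(max(p0, lo), hi)
  for (iter in 1:100) {
    fv <- f(p0)
    if (fv > 0) lo <- p0 else hi <- p0
    Z <- pi + (1 - pi) * p0^alpha
    u <- (1 - pi) * alpha * p0^(alpha - 1)
    uprime <- (1 - pi) * alpha * (alpha - 1) * p0^(alpha - 2)
    fprime <- W0 * (uprime * Z - u * u) / Z^2 - Wp * alpha / p0^2 - S / (1 - p0)^2
    step <- if (is.finite(fprime) && fprime < 0) -fv / fprime else NA_real_
    p0_new <- if (!is.na(step)) p0 + step else NA_real_
    if (is.na(p0_new) || p0_new <= lo || p0_new >= hi) p0_new <- (lo + hi) / 2
    if (abs(p0_new - p0) < tol) { p0 <- p0_new; break }
    p0 <- p0_new
  }
  p0
}
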