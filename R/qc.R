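#' Quality-control features of a discretization
#'
#' Extracts the five summary statistics that characterize the quality
#' of a discretization:
#' \describe{
#'   \item{q_high_to_low}{transition matrix entry from the 'high' to
#'     the 'low' state (an indicator of target size: sharp peaks leave
#'     the high state abruptly).}
#'   \item{min_snr}{minimum over replicates of the ratio of the
#'     high-state to medium-state mean emission rates (a
#'     signal-to-noise ratio; near 1 when a replicate carries no
#'     enrichment).}
#'   \item{target_fraction}{fraction of windows called 'high'.}
#'   \item{var_explained}{fraction of the variance of the per-window
#'     mean chip count explained by the called states (between-state
#'     over total sum of squares).}
#'   \item{replicate_correlation}{mean pairwise Pearson correlation
#'     between replicate count columns (1.0 with a warning when there
#'     is a single replicate).}
#' }
#'
#' @param fit an `hmm_fit` produced on `x`.
#' @param x the `count_matrix` that was discretized.
#' @return named numeric vector of the five features.
#' @export
qc_features <- function(fit, x) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(x, "count_matrix"))
  chips <- chip_counts(x)
  r <- ncol(chips)
  role <- fit$state_order
  i_low <- which(role == 0L); i_med <- which(role == 1L); i_high <- which(role == 2L)
  q_high_to_low <- fit$params$Q[i_high, i_low]
  rates <- state_mean_rates(fit$params)
  min_snr <- min(rates[i_high, ] / pmax(rates[i_med, ], .Machine$double.xmin))
  called <- role[fit$viterbi_path]
  target_fraction <- mean(called == 2L)
  var_explained <- variance_explained(rowMeans(chips), called)
  if (r >= 2L) {
    cc <- suppressWarnings(stats::cor(chips))
    pair <- cc[upper.tri(cc)]
    pair[is.na(pair)] <- 0
    replicate_correlation <- mean(pair)
  } else {
    warning("single replicate: replicate_correlation set to 1")
    replicate_correlation <- 1.0
  }
  c(q_high_to_low = q_high_to_low, min_snr = min_snr,
    target_fraction = target_fraction, var_explained = var_explained,
    replicate_correlation = replicate_correlation)
}

#' Build a labeled synthetic training corpus for quality control
#'
#' Generates a balanced corpus of discretization feature vectors.
#' Positive cases are simulated replicated experiments with true
#' enrichment and randomized depths, shapes and state separations.
#' Negative cases emulate the two common failure modes: (a)
#' enrichment-free profiles treated as ChIP (as when no
#' immunoprecipitation took place), and (b) non-replicate profiles
#' paired as replicates (each replicate follows its own independent
#' target set). Every case is discretized and passed through
#' [qc_features()]. Cases whose simulation or discretization fails
#' are dropped with a message and the corpus re-balanced.
#'
#' @param n_positive,n_negative number of cases per class.
#' @param seed integer seed; the corpus is fully reproducible from it.
#' @param n_windows windows per simulated case.
#' @param r replicates per case.
#' @param max_iter Baum-Welch iteration cap per case.
#' @return data.frame with the five feature columns and a `label`
#'   factor (`"fail"`, `"pass"`).
#' @export
build_training_corpus <- function(n_positive = 200L, n_negative = 200L,
                                  seed = 1L, n_windows = 1500L, r = 2L,
                                  max_iter = 25L) {
  set.seed(seed)
  n_tot <- n_positive + n_negative
  label <- rep(c("pass", "fail"), c(n_positive, n_negative))
  # case-level randomized conditions, drawn up-front for reproducibility
  low_m <- stats::runif(n_tot, 1.5, 3)
  med_f <- stats::runif(n_tot, 2.5, 4)
  high_f <- stats::runif(n_tot, 3, 6)
  alpha <- stats::runif(n_tot, 2, 6)
  piz <- stats::runif(n_tot, 0.05, 0.20)
  depth <- stats::runif(n_tot, 0.5, 2)
  ctrl_m <- stats::runif(n_tot, 3, 6)
  neg_type_a <- rep(FALSE, n_tot)
  neg_idx <- which(label == "fail")
  neg_type_a[neg_idx[seq_len(floor(length(neg_idx) / 2))]] <- TRUE
  case_seed <- sample.int(2^31 - 2L, n_tot)
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    means <- if (neg_type_a[i]) rep(ctrl_m[i], 3) else
      low_m[i] * c(1, med_f[i], med_f[i] * high_f[i])
    cfg <- sim_config(n_windows = n_windows, n_chrom = 1L, r = r,
                      pi = piz[i], alpha = alpha[i],
                      control_mean = ctrl_m[i],
                      state_means = means * depth[i],
                      independent_replicates = (label[i] == "fail" && !neg_type_a[i]),
                      seed = case_seed[i])
    feats <- tryCatch({
      sim <- simulate_chip(cfg)
      dp <- suppressWarnings(discretize(sim$counts, max_iter = max_iter,
                                        tol = 1e-4))
      dp$features
    }, error = function(e) {
      message("dropping corpus case ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(feats)) rows[[i]] <- c(feats, case = i)
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- as.data.frame(do.call(rbind, rows[keep]))
  out$case <- NULL
  out$label <- factor(label[keep], levels = c("fail", "pass"))
  n_by <- table(out$label)
  if (n_by["pass"] != n_positive || n_by["fail"] != n_negative)
    message("corpus is unbalanced after drops: ",
            n_by["pass"], " pass / ", n_by["fail"], " fail")
  out
}

stratified_folds <- function(label, folds, seed) {
  set.seed(seed)
  fold <- integer(length(label))
  for (lv in levels(label)) {
    idx <- sample(which(label == lv))
    if (length(idx) < 2L * folds)
      stop("cannot build ", folds, " stratified folds with ",
           length(idx), " examples of class '", lv, "'")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train the quality-control classifier
#'
#' Standardizes the five features, grid-searches the two
#' hyperparameters of a radial-basis-function support vector machine
#' (cost and kernel width) by stratified k-fold cross-validation, and
#' refits the best configuration on the full corpus.
#'
#' @param corpus data.frame from [build_training_corpus()] (five
#'   feature columns plus `label`).
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @param folds number of cross-validation folds (default 10).
#' @param seed seed for fold assignment.
#' @return an object of class `qc_model`: list with the fitted `svm`,
#'   scaling constants, selected hyperparameters, `cv_accuracy` (mean
#'   held-out accuracy at the selected hyperparameters) and the full
#'   `cv_table`.
#' @export
train_qc <- function(corpus, cost_grid = 2^(0:6), gamma_grid = 2^(-4:1),
                     folds = 10L, seed = 1L) {
  if (folds < 2L) stop("'folds' must be at least 2")
  if (!"label" %in% names(corpus)) stop("'corpus' must have a 'label' column")
  label <- factor(corpus$label)
  if (nlevels(label) != 2L) stop("'label' must have exactly two classes")
  X <- as.matrix(corpus[, setdiff(names(corpus), "label"), drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values in corpus")
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  fold <- stratified_folds(label, folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold != k
      m <- e1071::svm(Xs[tr, , drop = FALSE], label[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
      pred <- stats::predict(m, Xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == label[!tr])
    }
    acc[g] <- correct / length(label)
  }
  best <- which.max(acc)
  model <- e1071::svm(Xs, label, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(svm = model, center = center, scale = scale_,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best],
                 cv_table = cbind(grid, accuracy = acc),
                 feature_names = colnames(X)),
            class = "qc_model")
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf("qc_model: RBF SVM (cost=%g, gamma=%g), CV accuracy %.3f\n",
              x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Classify a discretization as accepted or rejected
#'
#' Applies the trained quality-control model to a feature vector. The
#' verdict is all-or-none for the whole profile: either the
#' discretization is accepted or it is rejected as a whole. The
#' decision value is the signed distance to the margin, positive when
#' accepted.
#'
#' @param model a `qc_model` from [train_qc()].
#' @param features named numeric vector from [qc_features()].
#' @return an object of class `qc_verdict`: list with `accepted`,
#'   `decision_value` and `features`.
#' @export
qc_classify <- function(model, features) {
  stopifnot(inherits(model, "qc_model"))
  bad <- names(features)[!is.finite(features)]
  if (length(bad))
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  x <- matrix(features[model$feature_names], nrow = 1,
              dimnames = list(NULL, model$feature_names))
  xs <- scale(x, center = model$center, scale = model$scale)
  pred <- stats::predict(model$svm, xs, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  dv_name <- colnames(attr(pred, "decision.values"))
  # orient the decision value so positive means 'pass'
  if (startsWith(dv_name, "fail")) dv <- -dv
  structure(list(accepted = unname(pred == "pass"),
                 decision_value = unname(dv),
                 features = features),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("QC verdict: %s (decision value %.3f)\n",
              if (x$accepted) "accepted" else "REJECTED", x$decision_value))
  invisible(x)
}

#' Train the default synthetic quality-control model
#'
#' Convenience wrapper: builds a synthetic corpus and trains the RBF
#' SVM on it. This classifier is trained on simulated data only and is
#' not a substitute for a model trained on curated experimental
#' discretizations.
#'
#' @param n_per_class corpus size per class.
#' @param seed integer seed.
#' @param ... passed to [build_training_corpus()].
#' @return a `qc_model`.
#' @export
default_qc_model <- function(n_per_class = 60L, seed = 101L, ...) {
  corpus <- build_training_corpus(n_positive = n_per_class,
                                  n_negative = n_per_class, seed = seed, ...)
  train_qc(corpus, seed = seed)
}
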