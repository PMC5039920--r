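#' Simulation configuration for the generative discretization model
#'
#' Describes a synthetic replicated ChIP-seq experiment drawn from the
#' three-state hidden Markov model with zero-inflated
#' negative-multinomial emissions. States follow a sticky Markov
#' chain per chromosome; each mappable window draws a shared
#' Gamma-distributed intensity (the window's intrinsic ChIP bias,
#' shared by controls and replicates) and per-profile Poisson counts,
#' which makes counts marginally zero-inflated negative multinomial
#' within each state. With probability `pi` a window is unmappable and
#' zero in every profile.
#'
#' Defaults describe a moderately deep experiment with well-separated
#' states: two chromosomes of 5000 windows of 300 bp, two replicates,
#' 10% unmappable windows, shape 4, control mean 4 reads/window and
#' state means 2 / 8 / 32 reads/window per replicate.
#'
#' @param n_windows windows per chromosome.
#' @param n_chrom number of chromosomes.
#' @param window_size window width in bp.
#' @param r number of ChIP replicates.
#' @param pi zero-inflation (unmappable window) probability.
#' @param alpha shape of the shared Gamma intensity.
#' @param control_mean expected control reads per mappable window.
#' @param state_means expected chip reads per mappable window in the
#'   low, medium and high states (length 3; per replicate before
#'   `depth` scaling).
#' @param depth per-replicate depth scaling factors (length `r`).
#' @param Q 3x3 transition matrix of the state chain.
#' @param nu initial state distribution.
#' @param independent_replicates if `TRUE`, each replicate follows its
#'   own independent state sequence (emulating non-replicate profiles
#'   paired as replicates).
#' @param seed integer seed; all stochastic output is fully determined
#'   by it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_windows = 5000L, n_chrom = 2L, window_size = 300L,
                       r = 2L, pi = 0.10, alpha = 4,
                       control_mean = 4, state_means = c(2, 8, 32),
                       depth = rep(1, r),
                       Q = matrix(c(0.980, 0.015, 0.005,
                                    0.040, 0.940, 0.020,
                                    0.020, 0.080, 0.900),
                                  nrow = 3, byrow = TRUE),
                       nu = c(0.7, 0.2, 0.1),
                       independent_replicates = FALSE,
                       seed = 42L) {
  stopifnot(n_windows >= 1, n_chrom >= 1, r >= 1, length(state_means) == 3,
            length(depth) == r, all(abs(rowSums(Q) - 1) < 1e-8),
            abs(sum(nu) - 1) < 1e-8, pi >= 0, pi < 1, alpha > 0)
  structure(list(n_windows = as.integer(n_windows),
                 n_chrom = as.integer(n_chrom),
                 window_size = as.integer(window_size),
                 r = as.integer(r), pi = pi, alpha = alpha,
                 control_mean = control_mean, state_means = state_means,
                 depth = depth, Q = Q, nu = nu,
                 independent_replicates = independent_replicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sample_chain <- function(n, nu, Q) {
  x <- integer(n)
  x[1] <- sample.int(3L, 1L, prob = nu)
  for (i in seq_len(n - 1L)) x[i + 1L] <- sample.int(3L, 1L, prob = Q[x[i], ])
  x
}

#' Simulate hidden state sequences
#'
#' Samples the per-chromosome state chains of a [sim_config()]. Each
#' chromosome restarts from the initial distribution.
#'
#' @param config a [sim_config()].
#' @return integer matrix of states in `{1, 2, 3}`, one column per
#'   replicate if `independent_replicates`, else a single column,
#'   rows ordered chromosome by chromosome.
#' @export
simulate_states <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_seq <- if (config$independent_replicates) config$r else 1L
  vapply(seq_len(n_seq), function(j)
    unlist(lapply(seq_len(config$n_chrom), function(ch)
      sample_chain(config$n_windows, config$nu, config$Q))),
    integer(config$n_windows * config$n_chrom))
}

#' Simulate window counts given states
#'
#' Draws the control and replicate counts of every window: with
#' probability `pi` the window is unmappable (zero everywhere);
#' otherwise a shared Gamma(`alpha`, rate 1) intensity is drawn and
#' each profile's count is Poisson with rate `intensity * lambda`,
#' where `lambda = mean / alpha` for the profile's state-dependent
#' mean. Controls use the state-independent baseline mean. Marginally,
#' the replicate vector of a window in state `s` is zero-inflated
#' negative multinomial with probabilities determined by the state
#' means.
#'
#' @param states matrix from [simulate_states()].
#' @param config the same [sim_config()].
#' @return list with `counts` (a `count_matrix`, control column
#'   first), `states` and `config`.
#' @export
simulate_counts <- function(states, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(as.matrix(states))
  states <- as.matrix(states)
  mappable <- stats::runif(n) >= config$pi
  G <- stats::rgamma(n, shape = config$alpha, rate = 1)
  lam_ctrl <- config$control_mean / config$alpha
  ctrl <- ifelse(mappable, stats::rpois(n, G * lam_ctrl), 0L)
  chips <- matrix(0L, n, config$r)
  for (j in seq_len(config$r)) {
    st <- states[, min(j, ncol(states))]
    lam <- config$state_means[st] * config$depth[j] / config$alpha
    chips[, j] <- ifelse(mappable, stats::rpois(n, G * lam), 0L)
  }
  chrom_lengths <- stats::setNames(
    rep(config$n_windows * config$window_size, config$n_chrom),
    paste0("chr", seq_len(config$n_chrom)))
  grid <- window_grid(chrom_lengths, config$window_size)
  counts <- cbind(as.integer(ctrl), chips)
  colnames(counts) <- c("control1", paste0("chip", seq_len(config$r)))
  list(counts = count_matrix(grid, counts, c("control", rep("chip", config$r))),
       states = states, config = config)
}

#' Simulate a full synthetic experiment
#'
#' Composes [simulate_states()] and [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return as [simulate_counts()], an object of class `chip_sim`.
#' @examples
#' sim <- simulate_chip(sim_config(n_windows = 200, n_chrom = 1, seed = 7))
#' sim$counts
#' @export
simulate_chip <- function(config = sim_config()) {
  states <- simulate_states(config)
  out <- simulate_counts(states, config)
  class(out) <- "chip_sim"
  out
}

#' @export
print.chip_sim <- function(x, ...) {
  cat(sprintf("chip_sim: %d windows, %d replicate(s), seed %d\n",
              nrow(x$counts$counts), x$config$r, x$config$seed))
  invisible(x)
}

#' Emit simulated profiles as BED read files
#'
#' Writes one BED file of synthetic 36 bp single-end reads per profile
#' such that re-ingesting them through [build_count_matrix()]
#' reproduces the simulated count matrix exactly: each read's midpoint
#' falls in its window, and reads occupy distinct (position, strand)
#' keys so that duplicate removal removes nothing. Duplicate reads can
#' be injected explicitly to exercise deduplication. The ground-truth
#' states are written alongside as a TSV.
#'
#' @param sim a `chip_sim` from [simulate_chip()].
#' @param dir output directory (created if needed).
#' @param read_length synthetic read length in bp.
#' @param inject_duplicates number of extra exact copies of the first
#'   read of each profile to inject.
#' @return named list of written file paths (`controls`, `chips`,
#'   `truth`).
#' @export
emit_bed <- function(sim, dir, read_length = 36L, inject_duplicates = 0L) {
  stopifnot(inherits(sim, "chip_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- sim$counts
  w <- cm$grid$windows
  wsize <- cm$grid$window_size
  half <- read_length %/% 2L
  capacity <- 2L * (wsize - half)
  if (any(cm$counts > capacity))
    stop("window counts exceed the distinct-read capacity of ", capacity,
         "; increase the window size or reduce depth")
  paths <- character(ncol(cm$counts))
  for (jcol in seq_len(ncol(cm$counts))) {
    cnt <- cm$counts[, jcol]
    nz <- which(cnt > 0)
    ks <- sequence(cnt[nz]) - 1L         # 0..count-1 within each window
    widx <- rep(nz, cnt[nz])
    offset <- ks %/% 2L
    strand <- ifelse(ks %% 2L == 0L, "+", "-")
    start <- w$start[widx] + offset
    end <- start + read_length
    bed <- data.frame(chrom = w$chrom[widx], start = start, end = end,
                      name = ".", score = 0L, strand = strand,
                      stringsAsFactors = FALSE)
    if (inject_duplicates > 0L && nrow(bed) > 0L)
      bed <- rbind(bed[rep(1L, inject_duplicates), ], bed)
    f <- file.path(dir, paste0(colnames(cm$counts)[jcol], ".bed"))
    utils::write.table(bed, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[jcol] <- f
  }
  truth <- file.path(dir, "truth_states.tsv")
  states1 <- as.matrix(sim$states)
  df <- cbind(w, as.data.frame(states1))
  names(df) <- c("chrom", "start", "end",
                 paste0("state", seq_len(ncol(states1))))
  utils::write.table(df, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(controls = paths[cm$roles == "control"],
       chips = paths[cm$roles == "chip"],
       truth = truth,
       chrom_lengths = cm$grid$chrom_lengths)
}
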