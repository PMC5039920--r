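#' Pareto front of cumulative read capture
#'
#' Orders genomic windows from high to low read count and accumulates
#' the counts: the resulting concave non-decreasing curve is the
#' largest number of reads capturable by any given number of target
#' windows. Any discretization of the same counts, represented as the
#' point (number of targets, reads captured by the targets), lies on
#' or below this front.
#'
#' @param counts non-negative per-window read counts (typically the
#'   pooled chip column).
#' @return data.frame of class `pareto_curve` with columns `n_windows`
#'   and `cum_reads`.
#' @examples
#' pareto_front(c(5, 3, 1))  # cum_reads 5, 8, 9
#' @export
pareto_front <- function(counts) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  out <- data.frame(n_windows = seq_along(counts),
                    cum_reads = cumsum(sort(counts, decreasing = TRUE)))
  class(out) <- c("pareto_curve", "data.frame")
  out
}

#' Place a discretization on the Pareto plane
#'
#' Computes the coordinates of a discretization — the number of target
#' windows and the total reads they capture — and whether the point
#' attains the front.
#'
#' @param counts per-window read counts.
#' @param targets logical vector over windows, or integer indices of
#'   the target windows.
#' @param curve optional precomputed [pareto_front()] of `counts`.
#' @return list with `n_targets`, `reads_captured`, `on_front`.
#' @export
place_discretization <- function(counts, targets, curve = pareto_front(counts)) {
  idx <- if (is.logical(targets)) which(targets) else as.integer(targets)
  if (length(idx) && (min(idx) < 1 || max(idx) > length(counts)))
    stop("'targets' must index into 'counts'")
  k <- length(idx)
  reads <- sum(counts[idx])
  on_front <- if (k == 0) TRUE else reads >= curve$cum_reads[k] - 1e-9
  list(n_targets = k, reads_captured = reads, on_front = on_front)
}

#' Precision, recall and F1 from benchmark counts
#'
#' The arithmetic of a motif-reference benchmark: precision is the
#' number of peaks containing at least one motif divided by the total
#' number of peaks, recall is the number of motifs covered by peaks
#' divided by the number of motifs in the genome, and the F1 score is
#' the harmonic mean of precision and recall (0 when both are 0).
#'
#' @param n_peaks total number of peaks called.
#' @param n_peaks_with_motif peaks containing at least one motif.
#' @param n_motifs_covered motifs overlapped by at least one peak.
#' @param n_motifs motifs in the genome.
#' @return list with `precision`, `recall`, `f1` (and the four
#'   counts).
#' @examples
#' benchmark_metrics(54315, 25324, 27421, 85690)
#' @export
benchmark_metrics <- function(n_peaks, n_peaks_with_motif,
                              n_motifs_covered, n_motifs) {
  precision <- if (n_peaks > 0) n_peaks_with_motif / n_peaks else NA_real_
  recall <- if (n_motifs > 0) n_motifs_covered / n_motifs else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) 0 else NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(n_peaks = n_peaks, n_peaks_with_motif = n_peaks_with_motif,
       n_motifs_covered = n_motifs_covered, n_motifs = n_motifs,
       precision = precision, recall = recall, f1 = f1)
}

as_granges_intervals <- function(x, what) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "BED")
    return(gr)
  }
  if (is.data.frame(x)) {
    # 0-based half-open input
    return(GenomicRanges::GRanges(x$chrom,
                                  IRanges::IRanges(x$start + 1L, x$end)))
  }
  stop("'", what, "' must be a GRanges, a BED file path or a ",
       "chrom/start/end data.frame")
}

#' Benchmark peaks against a motif reference
#'
#' Counts the overlaps (at least 1 bp) between called peaks and a
#' reference set of motif occurrences, and derives precision, recall
#' and F1 via [benchmark_metrics()]. True and false positives are
#' peaks with and without a motif, respectively.
#'
#' @param peaks,motifs interval sets: `GRanges`, BED file paths, or
#'   data.frames with 0-based half-open `chrom`/`start`/`end`.
#' @param resize_peaks optional width in bp; peaks are resized to this
#'   width around their center before overlap (off by default).
#' @return list of class `motif_benchmark` (see
#'   [benchmark_metrics()]).
#' @export
motif_benchmark <- function(peaks, motifs, resize_peaks = NULL) {
  pk <- as_granges_intervals(peaks, "peaks")
  mt <- as_granges_intervals(motifs, "motifs")
  if (length(mt) == 0) stop("empty motif reference")
  if (!is.null(resize_peaks))
    pk <- GenomicRanges::resize(pk, width = resize_peaks, fix = "center")
  with_motif <- sum(GenomicRanges::countOverlaps(pk, mt, ignore.strand = TRUE) > 0)
  covered <- sum(GenomicRanges::countOverlaps(mt, pk, ignore.strand = TRUE) > 0)
  out <- benchmark_metrics(length(pk), with_motif, covered, length(mt))
  class(out) <- c("motif_benchmark", class(out))
  out
}

#' @export
print.motif_benchmark <- function(x, ...) {
  cat(sprintf("motif_benchmark: %d peaks, %d with motif; %d/%d motifs covered\n",
              x$n_peaks, x$n_peaks_with_motif, x$n_motifs_covered, x$n_motifs))
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Fraction of variance explained by a grouping
#'
#' One-way decomposition: between-group sum of squares divided by the
#' total sum of squares of the response. Used both as a
#' quality-control feature (response = mean chip count per window,
#' groups = called states) and to benchmark a discretization against
#' an external response such as RNA read counts. Defined as 0 when
#' the response has no variance.
#'
#' @param response numeric vector.
#' @param groups grouping labels, same length.
#' @return fraction in `[0, 1]`.
#' @examples
#' variance_explained(c(1, 1, 5, 5), c("a", "a", "b", "b"))  # 1
#' variance_explained(c(1, 1, 5, 5), c("a", "b", "a", "b"))  # 0
#' @export
variance_explained <- function(response, groups) {
  if (length(response) != length(groups))
    stop("'response' and 'groups' must have the same length")
  tot <- sum((response - mean(response))^2)
  if (tot == 0) return(0)
  gm <- tapply(response, groups, mean)
  ni <- tapply(response, groups, length)
  between <- sum(ni * (gm - mean(response))^2)
  min(max(between / tot, 0), 1)
}
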