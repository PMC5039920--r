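#' Fixed-step window grid over a genome
#'
#' Tiles each chromosome with half-open windows of constant width (the
#' last window of a chromosome may be shorter). Coordinates are 0-based
#' half-open throughout the package.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp;
#'   the order given is the canonical chromosome order of the grid.
#' @param window_size window width in bp (default 300).
#' @return an object of class `window_grid`: list with `window_size`,
#'   `chrom_lengths`, `windows` (data.frame chrom/start/end) and
#'   `blocks` (per-chromosome row ranges, used to treat chromosomes as
#'   independent chains).
#' @examples
#' window_grid(c(chr1 = 1000, chr2 = 650), window_size = 300)
#' @export
window_grid <- function(chrom_lengths, window_size = 300L) {
  if (length(window_size) != 1L || is.na(window_size) || window_size < 1)
    stop("'window_size' must be a positive integer")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a named vector")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  window_size <- as.integer(window_size)
  chroms <- names(chrom_lengths)
  n_win <- as.integer(ceiling(chrom_lengths / window_size))
  starts <- unlist(lapply(seq_along(chroms), function(i)
    seq.int(0L, by = window_size, length.out = n_win[i])), use.names = FALSE)
  ends <- pmin(starts + window_size,
               rep.int(as.integer(chrom_lengths), n_win))
  windows <- data.frame(
    chrom = rep.int(chroms, n_win),
    start = starts,
    end = ends,
    stringsAsFactors = FALSE
  )
  offset <- cumsum(c(0L, n_win[-length(n_win)]))
  blocks <- data.frame(chrom = chroms, from = offset + 1L,
                       to = offset + n_win, stringsAsFactors = FALSE)
  structure(list(window_size = window_size,
                 chrom_lengths = chrom_lengths,
                 windows = windows,
                 blocks = blocks),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %d bp over %d chromosome(s)\n",
              nrow(x$windows), x$window_size, nrow(x$blocks)))
  invisible(x)
}

#' Read mapped reads from BED, SAM or BAM
#'
#' Parses a file of mapped reads into a data.frame of 0-based half-open
#' intervals with strand. BED input is consumed as-is; SAM/BAM
#' coordinates (1-based inclusive) are converted on read. Unmapped,
#' secondary and supplementary alignments are skipped. A BED record
#' without a strand column is taken as `+`.
#'
#' @param path input file.
#' @param format one of `"auto"` (by extension), `"bed"`, `"sam"`,
#'   `"bam"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_mapped_reads <- function(path, format = c("auto", "bed", "sam", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension of ", path,
                          "; pass 'format' explicitly"))
  }
  if (format == "bed") read_reads_bed(path) else read_reads_sambam(path, format)
}

read_reads_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,   # back to 0-based
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

read_reads_sambam <- function(path, format) {
  bam <- path
  if (format == "sam") {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("malformed SAM file ", path, ": ",
                               conditionMessage(e)))
    on.exit(unlink(bam))
    # htslib drops unparseable records with a console warning only;
    # surface silent loss as a hard parse error
    n_lines <- sum(!startsWith(readLines(path), "@"))
    n_rec <- Rsamtools::countBam(bam)$records
    if (n_rec != n_lines)
      stop("malformed SAM file ", path, ": ", n_lines - n_rec,
           " record(s) could not be parsed")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "strand", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (length(rec$pos) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  data.frame(chrom = as.character(rec$rname),
             start = rec$pos - 1L,                    # 1-based -> 0-based
             end = rec$pos - 1L + width,
             strand = as.character(rec$strand),
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicates
#'
#' Keeps at most one read per (chromosome, 5'-position, strand) key:
#' reads mapping to the same location in the same orientation are
#' collapsed to the first one encountered. The 5' coordinate is the
#' start for `+` reads and the end for `-` reads, which makes the key
#' robust to 3'-end soft-clipping differences.
#'
#' @param reads data.frame as returned by [read_mapped_reads()].
#' @return the deduplicated data.frame, input order preserved.
#' @export
deduplicate_reads <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  five_prime <- ifelse(reads$strand == "-", reads$end, reads$start)
  key <- paste(reads$chrom, five_prime, reads$strand, sep = "\r")
  reads[!duplicated(key), , drop = FALSE]
}

#' Bin reads into a window grid by midpoint
#'
#' Each read increments the window containing its midpoint
#' `floor((start + end) / 2)`. Reads on chromosomes absent from the
#' grid are skipped with a summary warning (tolerating decoy contigs);
#' a midpoint beyond the declared chromosome length is assigned to the
#' last window with a warning.
#'
#' @param reads data.frame of mapped reads (0-based half-open).
#' @param grid a [window_grid()].
#' @return integer vector of per-window counts (length = number of grid
#'   windows), with attribute `skipped` giving the number of off-grid
#'   reads.
#' @export
bin_reads <- function(reads, grid) {
  stopifnot(inherits(grid, "window_grid"))
  n <- nrow(grid$windows)
  counts <- integer(n)
  on_grid <- reads$chrom %in% grid$blocks$chrom
  n_skip <- sum(!on_grid)
  if (n_skip > 0)
    warning(n_skip, " read(s) on chromosomes absent from the grid were skipped")
  reads <- reads[on_grid, , drop = FALSE]
  if (nrow(reads) > 0) {
    mid <- (reads$start + reads$end) %/% 2L
    blk <- grid$blocks[match(reads$chrom, grid$blocks$chrom), ]
    idx <- blk$from + mid %/% grid$window_size
    over <- idx > blk$to
    if (any(over)) {
      warning(sum(over), " read midpoint(s) beyond the declared chromosome ",
              "length; assigned to the last window")
      idx[over] <- blk$to[over]
    }
    tab <- tabulate(idx, nbins = n)
    counts <- as.integer(tab)
  }
  attr(counts, "skipped") <- n_skip
  counts
}

#' Build a window count matrix from read files
#'
#' Reads each profile, removes PCR duplicates per profile, bins by
#' midpoint, and assembles the per-window count matrix with control
#' columns first. Emits a sanity warning when the mean number of reads
#' per window of any profile is below 3, since the window size should
#' be chosen to give more than 3-4 mapped reads per window.
#'
#' @param control_paths,chip_paths character vectors of read files
#'   (BED/SAM/BAM); at least one of each is required for
#'   discretization.
#' @param chrom_lengths named vector of chromosome lengths; if `NULL`
#'   and `infer_lengths = TRUE`, lengths are inferred from the maximum
#'   read coordinate per chromosome.
#' @param window_size window width in bp.
#' @param format passed to [read_mapped_reads()].
#' @param infer_lengths allow inferring chromosome lengths from the
#'   reads.
#' @param deduplicate remove PCR duplicates before binning.
#' @return an object of class `count_matrix`: list with `grid`,
#'   `counts` (n windows by m profiles), `roles` (`"control"` or
#'   `"chip"` per column).
#' @export
build_count_matrix <- function(control_paths, chip_paths,
                               chrom_lengths = NULL, window_size = 300L,
                               format = "auto", infer_lengths = FALSE,
                               deduplicate = TRUE) {
  if (length(control_paths) < 1L || length(chip_paths) < 1L)
    stop("need at least one control and one ChIP read file")
  paths <- c(control_paths, chip_paths)
  roles <- c(rep("control", length(control_paths)),
             rep("chip", length(chip_paths)))
  read_sets <- lapply(paths, read_mapped_reads, format = format)
  if (deduplicate) read_sets <- lapply(read_sets, deduplicate_reads)
  seen <- unique(unlist(lapply(read_sets, function(r) unique(r$chrom))))
  if (is.null(chrom_lengths)) {
    if (!infer_lengths)
      stop("'chrom_lengths' is required unless 'infer_lengths = TRUE'")
    chrom_lengths <- vapply(seen, function(ch)
      max(unlist(lapply(read_sets, function(r) r$end[r$chrom == ch])), 0L),
      numeric(1))
  } else if (infer_lengths) {
    # keep declared lengths, but fail loudly on chromosomes we know nothing about
  } else {
    missing <- setdiff(seen, names(chrom_lengths))
    if (length(missing))
      warning("reads on chromosome(s) absent from 'chrom_lengths' will be ",
              "skipped: ", paste(missing, collapse = ", "))
  }
  grid <- window_grid(chrom_lengths, window_size)
  cols <- lapply(read_sets, function(r) suppressWarnings(bin_reads(r, grid)))
  counts <- do.call(cbind, lapply(cols, as.integer))
  colnames(counts) <- paste0(roles, c(seq_along(control_paths), seq_along(chip_paths)))
  mean_per_window <- colMeans(counts)
  if (any(mean_per_window < 3))
    warning("mean reads per window below 3 for profile(s) ",
            paste(colnames(counts)[mean_per_window < 3], collapse = ", "),
            "; consider a larger window size")
  count_matrix(grid, counts, roles)
}

#' Construct a count matrix object
#'
#' @param grid a [window_grid()].
#' @param counts integer matrix, windows by profiles.
#' @param roles character vector, `"control"` or `"chip"` per column.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(grid, counts, roles) {
  stopifnot(inherits(grid, "window_grid"))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(grid$windows))
    stop("'counts' must have one row per grid window")
  if (ncol(counts) != length(roles))
    stop("'roles' must have one entry per count column")
  if (!all(roles %in% c("control", "chip")))
    stop("roles must be 'control' or 'chip'")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(roles, stats::ave(seq_along(roles), roles, FUN = seq_along))
  structure(list(grid = grid, counts = counts, roles = roles),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d windows x %d profiles (%d control, %d chip)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$roles == "control"), sum(x$roles == "chip")))
  invisible(x)
}

#' Chip and control column accessors
#' @param x a `count_matrix`.
#' @return integer matrix of the requested columns.
#' @export
chip_counts <- function(x) x$counts[, x$roles == "chip", drop = FALSE]

#' @rdname chip_counts
#' @export
control_counts <- function(x) x$counts[, x$roles == "control", drop = FALSE]

#' Write / read a count matrix as TSV
#'
#' The TSV has columns chrom, start, end followed by one column per
#' profile, named `<profile>:<role>` in the header.
#'
#' @param x a `count_matrix`.
#' @param path output (input) file.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- cbind(x$grid$windows,
              as.data.frame(x$counts))
  names(df) <- c("chrom", "start", "end",
                 paste0(colnames(x$counts), ":", x$roles))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  prof <- names(df)[-(1:3)]
  split_names <- strsplit(prof, ":", fixed = TRUE)
  roles <- vapply(split_names, `[`, "", 2L)
  if (any(is.na(roles)))
    stop("count matrix header must name profiles as '<name>:<role>'")
  lens <- tapply(df$end, df$chrom, max)
  chroms <- unique(df$chrom)
  chrom_lengths <- as.numeric(lens[chroms])
  names(chrom_lengths) <- chroms
  wsize <- df$end[1L] - df$start[1L]
  grid <- window_grid(chrom_lengths, wsize)
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  colnames(counts) <- vapply(split_names, `[`, "", 1L)
  count_matrix(grid, counts, roles)
}
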