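#' @title Assembly-level computations
#' @description Genome-size estimation from a k-mer frequency histogram and
#'   telomere detection by terminal motif scanning.
#' @name assembly_qc
NULL

#' Read a k-mer depth histogram
#'
#' Two-column whitespace-separated text, `depth n_kmers` per row (the
#' jellyfish/meryl `histo` dialect). Depths must be >= 1 and strictly
#' increasing.
#'
#' @param path File path.
#' @param k The k-mer length the histogram was computed at (metadata).
#' @return Data frame with columns `depth`, `n_kmers` and attribute `k`.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  if (!file.exists(path)) stop("histogram file not found: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("depth", "n_kmers"))
  validate_histogram(tab)
  attr(tab, "k") <- as.integer(k)
  tab
}

validate_histogram <- function(hist) {
  if (!is.data.frame(hist) || !all(c("depth", "n_kmers") %in% names(hist)))
    stop("histogram needs columns 'depth' and 'n_kmers'")
  if (!nrow(hist)) stop("empty k-mer histogram")
  if (any(hist$depth < 1)) stop("depths must be >= 1")
  if (any(hist$n_kmers < 0)) stop("k-mer counts must be >= 0")
  if (is.unsorted(hist$depth, strictly = TRUE))
    stop("depths must be strictly increasing")
  invisible(hist)
}

#' Estimate genome size from a k-mer histogram
#'
#' Implements `genome size = k-mer number / expectation of k-mer depth`,
#' with the depth expectation taken as the modal depth of the main coverage
#' peak: error k-mers at low depth are excluded from the mode search by
#' skipping everything up to the first local minimum of the histogram, but
#' are by default *included* in the total k-mer number (set
#' `exclude_error = TRUE` to drop depths below the minimum from the total
#' as well). With `mean_mode = TRUE` the weighted mean depth above the error
#' minimum replaces the mode.
#'
#' @param hist Data frame with columns `depth`, `n_kmers`.
#' @param exclude_error Drop depths at or below the error minimum from the
#'   total k-mer number (default `FALSE`, per the stated formula).
#' @param mean_mode Use the weighted mean depth above the error minimum
#'   instead of the modal depth.
#' @return List with `size_bp`, `peak_depth`, `total_kmers`.
#' @export
estimate_genome_size <- function(hist, exclude_error = FALSE,
                                 mean_mode = FALSE) {
  validate_histogram(hist)
  d <- hist$depth; n <- as.numeric(hist$n_kmers)
  # first local minimum: the first depth after which counts rise again
  rise <- which(diff(n) > 0)
  if (!length(rise))
    stop("no coverage peak: histogram is monotonically non-increasing")
  valley <- rise[1]
  after <- seq(valley + 1L, length(d))
  peak_depth <- if (mean_mode) {
    sum(d[after] * n[after]) / sum(n[after])
  } else {
    d[after][which.max(n[after])]
  }
  tot_idx <- if (exclude_error) after else seq_along(d)
  total <- sum(d[tot_idx] * n[tot_idx])
  list(size_bp = total / peak_depth, peak_depth = peak_depth,
       total_kmers = total)
}

#' Find telomeric repeat arrays at sequence ends
#'
#' Counts non-overlapping occurrences of the telomere motif in forward
#' orientation within the left terminal window, and of its reverse
#' complement within the right terminal window, of every sequence. A hit is
#' emitted per end reaching `min_copies`. Characters outside the IUPAC DNA
#' set trigger a warning and behave as mismatches.
#'
#' @param assembly Path to a FASTA file, or a [Biostrings::DNAStringSet] /
#'   named character vector of sequences.
#' @param motif Telomeric repeat unit (default vertebrate `TTAGGG`).
#' @param window_bp Terminal window scanned at each end (default 10000).
#' @param min_copies Minimum motif copies for a hit (default 50).
#' @return Data frame of hits: `seqid`, `end` (`"left"`/`"right"`),
#'   `copies`, `window_bp`.
#' @export
find_telomeres <- function(assembly, motif = "TTAGGG", window_bp = 10000L,
                           min_copies = 50L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  window_bp <- as.integer(window_bp)
  if (window_bp < nchar(motif) * min_copies)
    stop("window_bp must be >= |motif| * min_copies")
  seqs <- if (is.character(assembly) && length(assembly) == 1L &&
              file.exists(assembly)) {
    Biostrings::readBStringSet(assembly)
  } else if (methods::is(assembly, "XStringSet")) {
    Biostrings::BStringSet(assembly)
  } else if (is.character(assembly)) {
    Biostrings::BStringSet(assembly)
  } else stop("cannot interpret 'assembly' as sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  motif <- toupper(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  iupac <- c(strsplit("ACGTRYSWKMBDHVN", "")[[1]])
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    chars <- unique(strsplit(s, "")[[1]])
    if (length(setdiff(chars, iupac)))
      warning("sequence '", names(seqs)[i],
              "' contains non-IUPAC characters; treated as mismatches")
    len <- nchar(s)
    w <- min(window_bp, len)
    left <- substr(s, 1L, w)
    right <- substr(s, len - w + 1L, len)
    nl <- count_nonoverlapping(left, motif)
    nr <- count_nonoverlapping(right, rc)
    if (nl >= min_copies)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = names(seqs)[i], end = "left", copies = nl, window_bp = w,
        stringsAsFactors = FALSE)
    if (nr >= min_copies)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = names(seqs)[i], end = "right", copies = nr, window_bp = w,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(seqid = character(0), end = character(0),
                      copies = integer(0), window_bp = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

count_nonoverlapping <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  sum(m > 0)
}

#' Summarize telomere hits for one assembly
#'
#' @param hits Data frame from [find_telomeres()].
#' @param n_sequences Number of sequences in the assembly.
#' @param seqids Optional sequence ids (to name the missing ends).
#' @return List with `total` (telomere count, at most `2 * n_sequences`),
#'   `t2t` (sequences with both ends hit), and `missing` (data frame of
#'   ends lacking a telomere, when `seqids` given).
#' @export
count_telomeres <- function(hits, n_sequences, seqids = NULL) {
  n_sequences <- as.integer(n_sequences)
  total <- nrow(hits)
  if (total > 2L * n_sequences)
    stop("more hits than sequence ends: at most one hit per end allowed")
  both <- if (total) {
    tab <- table(hits$seqid)
    sum(tab == 2L)
  } else 0L
  missing <- NULL
  if (!is.null(seqids)) {
    grid <- expand.grid(seqid = seqids, end = c("left", "right"),
                        stringsAsFactors = FALSE)
    key <- paste(grid$seqid, grid$end)
    have <- paste(hits$seqid, hits$end)
    missing <- grid[!key %in% have, , drop = FALSE]
    missing <- missing[order(missing$seqid, missing$end), , drop = FALSE]
    rownames(missing) <- NULL
  }
  list(total = total, t2t = both, missing = missing)
}
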