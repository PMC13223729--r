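#' @title Chromosome painting
#' @description Assigns ancestral-chromosome identities ("colors") to genes
#'   from best-hit tables, applies the per-chromosome minimum-count filter,
#'   and segments chromosomes into contiguous color blocks.
#' @name painting
NULL

#' Construct a painted karyotype
#'
#' A painted karyotype holds one species' gene table (sorted by chromosome
#' and start) plus the lineage's expected copies per ancestral chromosome
#' (1 for lineages without an extra whole-genome duplication, 2 after one,
#' 4 after two). Uncolored genes carry `NA`.
#'
#' @param genes Data frame with columns `chromosome`, `start`, `end`,
#'   `gene_id` and `color` (a `true_color` column is accepted as the color).
#'   Optional columns `e_value` and `bit_score` are kept.
#' @param species Species label (taken from a `species` column if present).
#' @param ploidy Expected copies per ancestral chromosome: 1, 2 or 4.
#' @return An object of class `painted_karyotype`.
#' @export
painted_karyotype <- function(genes, species = NULL, ploidy = 1L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"color" %in% names(genes) && "true_color" %in% names(genes))
    names(genes)[names(genes) == "true_color"] <- "color"
  need <- c("chromosome", "start", "end", "gene_id", "color")
  if (!all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (is.null(species))
    species <- if ("species" %in% names(genes) && nrow(genes))
      genes$species[1] else "species"
  if (!ploidy %in% c(1L, 2L, 4L)) stop("ploidy must be 1, 2 or 4")
  if (any(genes$start >= genes$end))
    stop("gene coordinates must satisfy start < end (0-based, half-open)")
  keep <- intersect(c("chromosome", "start", "end", "gene_id", "color",
                      "e_value", "bit_score"), names(genes))
  genes <- genes[order(genes$chromosome, genes$start), keep, drop = FALSE]
  rownames(genes) <- NULL
  structure(list(species = species, ploidy = as.integer(ploidy),
                 genes = genes, blocks = NULL),
            class = "painted_karyotype")
}

#' @export
print.painted_karyotype <- function(x, ...) {
  cat("<painted_karyotype> ", x$species, ": ",
      length(unique(x$genes$chromosome)), " chromosomes, ",
      nrow(x$genes), " genes (", sum(!is.na(x$genes$color)), " colored), ",
      "ploidy ", x$ploidy, "\n", sep = "")
  invisible(x)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the 12 standard tab-separated columns. Rows with non-numeric
#' scores are rejected with their line number.
#'
#' @param path Path to the tab-separated file.
#' @return Data frame with the standard column names (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 12L)
    stop("expected 12 tab-separated columns, found ", ncol(raw))
  raw <- raw[, 1:12]
  names(raw) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(raw[[cn]]))
    if (length(bad))
      stop("malformed ", cn, " at line ", bad[1], ": '", raw[[cn]][bad[1]], "'")
    raw[[cn]] <- v
  }
  raw
}

#' Resolve best hits per query
#'
#' Hits above the E-value threshold are discarded; per query, the hit with
#' the highest bit score is retained, ties broken by lowest E-value and then
#' by lexicographically smallest subject id.
#'
#' @param hits Data frame as returned by [read_blast_tab()] (only `qseqid`,
#'   `sseqid`, `evalue`, `bitscore` are used).
#' @param e_max E-value threshold (default `1e-10`).
#' @return Named character vector: query id -> subject id.
#' @export
resolve_best_hits <- function(hits, e_max = 1e-10) {
  stopifnot(e_max > 0)
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stop("hits need columns: ", paste(need, collapse = ", "))
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  stats::setNames(best$sseqid, best$qseqid)
}

#' Assign colors to genes from resolved hits
#'
#' @param genes Gene data frame (see [painted_karyotype()]; a `color` column
#'   is added/overwritten).
#' @param hit_map Named character vector query -> subject
#'   (from [resolve_best_hits()]).
#' @param ancestor_map Named character vector subject -> color (or ancestral
#'   chromosome id). Must cover every subject in `hit_map`.
#' @return The gene data frame with a `color` column; genes without a
#'   surviving hit get `NA`. Input order is preserved.
#' @export
assign_colors <- function(genes, hit_map, ancestor_map) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  subj <- unname(hit_map[genes$gene_id])
  known <- !is.na(subj)
  missing <- setdiff(unique(subj[known]), names(ancestor_map))
  if (length(missing))
    stop("subject(s) absent from ancestor map: ",
         paste(missing, collapse = ", "))
  genes$color <- NA_character_
  genes$color[known] <- unname(ancestor_map[subj[known]])
  genes
}

#' Filter out minor colors per chromosome
#'
#' On each chromosome independently, every color whose total gene count on
#' that chromosome is strictly below `min_genes` has all its genes set to
#' uncolored; colors at or above the threshold are untouched. Chromosome and
#' gene order are unchanged.
#'
#' @param karyotype A `painted_karyotype`.
#' @param min_genes Minimum gene count per color per chromosome (default 20).
#' @return The filtered `painted_karyotype` (blocks are invalidated).
#' @export
filter_minor_colors <- function(karyotype, min_genes = 20L) {
  stopifnot(inherits(karyotype, "painted_karyotype"), min_genes >= 1L)
  g <- karyotype$genes
  if (nrow(g)) {
    counts <- table(g$chromosome, g$color)
    for (chr in rownames(counts)) {
      weak <- colnames(counts)[counts[chr, ] > 0 & counts[chr, ] < min_genes]
      if (length(weak)) {
        drop <- g$chromosome == chr & !is.na(g$color) & g$color %in% weak
        g$color[drop] <- NA_character_
      }
    }
  }
  karyotype$genes <- g
  karyotype$blocks <- NULL
  karyotype
}

# run-length blocks over a color sequence (uncolored entries already removed)
runs_to_blocks <- function(colors) {
  if (!length(colors))
    return(data.frame(color = character(0), gene_count = integer(0)))
  r <- rle(colors)
  data.frame(color = r$values, gene_count = r$lengths,
             stringsAsFactors = FALSE)
}

# sliding majority vote over the w nearest colored neighbours; ties keep the
# original color
smooth_colors <- function(colors, w) {
  if (w <= 1L || length(colors) < 2L) return(colors)
  half <- (w - 1L) %/% 2L
  n <- length(colors)
  out <- colors
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    tab <- table(colors[lo:hi])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) out[i] <- top
  }
  out
}

#' Segment a painted karyotype into color blocks
#'
#' Uncolored genes are transparent: they never break a block. With a
#' smoothing window `w > 1`, each colored gene's color is first replaced by
#' the majority color among its `w` nearest colored neighbours (ties keep
#' the original color); maximal same-color runs then become blocks.
#'
#' @param karyotype A `painted_karyotype`.
#' @param smoothing_window Odd window size (default 1 = no smoothing).
#' @return The `painted_karyotype` with a `blocks` data frame: `chromosome`,
#'   `color`, `gene_count`, `first_index`, `last_index`, `start`, `end`.
#' @export
segment_blocks <- function(karyotype, smoothing_window = 1L) {
  stopifnot(inherits(karyotype, "painted_karyotype"))
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L)
    stop("smoothing_window must be an odd count >= 1")
  g <- karyotype$genes
  blocks <- list()
  for (chr in unique(g$chromosome)) {
    idx <- which(g$chromosome == chr & !is.na(g$color))
    if (!length(idx)) next
    cols <- smooth_colors(g$color[idx], w)
    r <- rle(cols)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks[[chr]] <- data.frame(
      chromosome = chr, color = r$values, gene_count = r$lengths,
      first_index = idx[starts], last_index = idx[ends],
      start = g$start[idx[starts]], end = g$end[idx[ends]],
      stringsAsFactors = FALSE)
  }
  karyotype$blocks <- if (length(blocks)) {
    out <- do.call(rbind, blocks); rownames(out) <- NULL; out
  } else data.frame(chromosome = character(0), color = character(0),
                    gene_count = integer(0), first_index = integer(0),
                    last_index = integer(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  karyotype
}

#' Chromosome-by-color gene count matrix
#'
#' @param x A `painted_karyotype` (colored genes only) or a gene data frame.
#' @param labels Optional color universe for the columns (defaults to the
#'   colors present).
#' @return Integer matrix, rows = chromosomes (sorted), cols = colors.
#' @export
composition_matrix <- function(x, labels = NULL) {
  g <- if (inherits(x, "painted_karyotype")) x$genes else
    as.data.frame(x, stringsAsFactors = FALSE)
  g <- g[!is.na(g$color), , drop = FALSE]
  chroms <- sort(unique(g$chromosome))
  cols <- labels %||% sort(unique(g$color))
  m <- matrix(0L, nrow = length(chroms), ncol = length(cols),
              dimnames = list(chroms, cols))
  if (nrow(g)) {
    unknown <- setdiff(unique(g$color), cols)
    if (length(unknown))
      stop("colors outside the label universe: ",
           paste(unknown, collapse = ", "))
    tab <- table(g$chromosome, g$color)
    m[rownames(tab), colnames(tab)] <- tab
  }
  m
}
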