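#' @title Readers and writers
#' @description Gene coordinates from BED or GFF3, painted gene tables as
#'   TSV/BED, and round-tripping helpers. Internal coordinates are 0-based,
#'   half-open; GFF3 (1-based, inclusive) is converted on read, BED is taken
#'   as-is.
#' @name io
NULL

#' Read gene coordinates from BED
#'
#' @param path BED file (>= 4 columns; the name field is the gene id, or
#'   `gene_id|color` as written by [write_sim_tables()]).
#' @return Data frame: `chromosome`, `start`, `end`, `gene_id` and, when the
#'   name field encodes one, `color`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  out <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                    end = GenomicRanges::end(gr),
                    gene_id = nm, stringsAsFactors = FALSE)
  if (any(grepl("|", nm, fixed = TRUE))) {
    parts <- strsplit(nm, "|", fixed = TRUE)
    out$gene_id <- vapply(parts, `[`, character(1), 1L)
    out$color <- vapply(parts, function(p)
      if (length(p) > 1L) p[2] else NA_character_, character(1))
  }
  out
}

#' Read gene coordinates from GFF3
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @param id_attribute Attribute holding the gene id (default `"ID"`).
#' @return Data frame: `chromosome`, `start` (converted to 0-based), `end`,
#'   `gene_id`.
#' @export
read_gene_gff3 <- function(path, feature_type = "gene", id_attribute = "ID") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- GenomicRanges::mcols(gr)[[id_attribute]]
  if (is.null(ids)) stop("attribute '", id_attribute, "' not found in GFF3")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = as.character(ids), stringsAsFactors = FALSE)
}

#' Write / read a painted gene table (TSV)
#'
#' Columns: `species`, `chromosome`, `start`, `end`, `gene_id`, `color` and,
#' when available, `e_value`, `bit_score`. Uncolored genes carry `NA`.
#'
#' @param karyotype A `painted_karyotype`.
#' @param path File path.
#' @return `read_painted_tsv` returns a `painted_karyotype`;
#'   `write_painted_tsv` invisibly returns `path`.
#' @export
write_painted_tsv <- function(karyotype, path) {
  stopifnot(inherits(karyotype, "painted_karyotype"))
  g <- karyotype$genes
  g <- cbind(data.frame(species = karyotype$species,
                        stringsAsFactors = FALSE), g)
  attr_line <- paste0("# ploidy=", karyotype$ploidy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(g, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_painted_tsv
#' @export
read_painted_tsv <- function(path) {
  if (!file.exists(path)) stop("painted table not found: ", path)
  first <- readLines(path, n = 1L)
  ploidy <- 1L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("ploidy=([0-9]+)", first))[[1]]
    if (length(m) == 2L) ploidy <- as.integer(m[2])
  }
  g <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  painted_karyotype(g, ploidy = ploidy)
}
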