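#' @title Ancestral karyotype definitions
#' @description Containers describing an ancestral karyotype as an ordered set
#'   of chromosomes, each composed of colored gene segments. The 13 teleost
#'   proto-chromosomes are conventionally labelled `a`-`m`; after the
#'   teleost-specific (third round) whole-genome duplication and 8 major
#'   rearrangements the teleost ancestor is modelled with 24 chromosomes.
#' @name ancestor
NULL

#' The 13 teleost proto-chromosome color labels
#' @return Character vector `a`-`m`.
#' @export
teleost_colors <- function() letters[1:13]

#' Construct an ancestral karyotype definition
#'
#' An ancestor definition is an ordered list of chromosomes, each an ordered
#' set of `(color, gene_count)` segments. Colors are display labels drawn from
#' a fixed universe (the 13 teleost proto-chromosome letters by default);
#' chromosome ids are the labels used for gene-level painting.
#'
#' @param chromosomes Named list; each element a data frame (or list coercible
#'   to one) with columns `color` and `gene_count`.
#' @param name Label for the definition (e.g. `"teleost_24"`).
#' @param colors Color universe the segment colors must come from.
#' @param rearrangements Optional data frame recording the rearrangements
#'   applied while laying out the definition (metadata only).
#' @return An object of class `ancestor_def`.
#' @export
ancestor_definition <- function(chromosomes, name = "ancestor",
                                colors = teleost_colors(),
                                rearrangements = NULL) {
  if (!is.list(chromosomes) || length(chromosomes) < 1L)
    stop("'chromosomes' must be a non-empty list")
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)) ||
      any(!nzchar(names(chromosomes))))
    stop("chromosome ids must be unique, non-empty names")
  chromosomes <- lapply(chromosomes, function(seg) {
    seg <- as.data.frame(seg, stringsAsFactors = FALSE)
    if (!all(c("color", "gene_count") %in% names(seg)))
      stop("each chromosome needs 'color' and 'gene_count' columns")
    if (nrow(seg) < 1L)
      stop("every chromosome must carry at least one color segment")
    if (any(seg$gene_count < 1L))
      stop("segment gene counts must be >= 1")
    data.frame(color = as.character(seg$color),
               gene_count = as.integer(seg$gene_count),
               stringsAsFactors = FALSE)
  })
  used <- unique(unlist(lapply(chromosomes, `[[`, "color")))
  if (!all(used %in% colors))
    stop("segment colors outside the declared color universe: ",
         paste(setdiff(used, colors), collapse = ", "))
  structure(list(name = name, chromosomes = chromosomes, colors = colors,
                 rearrangements = rearrangements),
            class = "ancestor_def")
}

#' @export
print.ancestor_def <- function(x, ...) {
  sizes <- ancestor_chromosome_sizes(x)
  cat("<ancestor_def> ", x$name, ": ", length(x$chromosomes),
      " chromosomes, ", sum(sizes), " genes\n", sep = "")
  invisible(x)
}

#' Per-chromosome gene counts of an ancestor definition
#' @param ancestor An `ancestor_def`.
#' @return Named integer vector of gene counts.
#' @export
ancestor_chromosome_sizes <- function(ancestor) {
  stopifnot(inherits(ancestor, "ancestor_def"))
  vapply(ancestor$chromosomes, function(s) sum(s$gene_count), integer(1))
}

#' Build the default teleost ancestral karyotype
#'
#' The 13 proto-chromosomes are duplicated (mirroring the teleost-specific
#' whole-genome duplication) and, for the canonical 24-chromosome layout,
#' 8 rearrangements are applied and recorded in the definition's metadata:
#' two fusions joining four of the duplicated copies into two two-color
#' chromosomes, and three reciprocal translocation pairs exchanging a quarter
#' segment between duplicate copies. Every chromosome carries one or two
#' colors and all 13 colors are represented.
#'
#' @param n_chrom Number of chromosomes (>= 13). `24` selects the canonical
#'   post-duplication layout; `13` the identity layout (one chromosome per
#'   color); other values lay out single-color chromosomes with colors
#'   recycled.
#' @param colors Exactly 13 distinct color labels.
#' @param genes_per_segment Marker density per color segment (>= 1).
#' @return An `ancestor_def` with chromosome ids `T01`, `T02`, ...
#' @examples
#' anc <- build_teleost_ancestor()
#' length(anc$chromosomes)           # 24
#' sum(ancestor_chromosome_sizes(anc))
#' @export
build_teleost_ancestor <- function(n_chrom = 24L, colors = teleost_colors(),
                                   genes_per_segment = 400L) {
  n_chrom <- as.integer(n_chrom)
  genes_per_segment <- as.integer(genes_per_segment)
  if (length(colors) != 13L || anyDuplicated(colors))
    stop("'colors' must be 13 distinct labels")
  if (genes_per_segment < 1L) stop("'genes_per_segment' must be >= 1")
  if (n_chrom < 13L)
    stop("cannot place all 13 colors on ", n_chrom, " chromosomes")
  g <- genes_per_segment
  seg <- function(color, n) data.frame(color = color, gene_count = as.integer(n),
                                       stringsAsFactors = FALSE)
  if (n_chrom == 24L) {
    if (g < 4L) stop("the 24-chromosome layout needs genes_per_segment >= 4")
    q <- as.integer(round(g / 4))  # translocated quarter segment
    chroms <- c(
      lapply(colors, seg, n = g),                          # T01..T13
      list(rbind(seg(colors[1], g), seg(colors[2], g)),    # T14 = fusion(a2,b2)
           rbind(seg(colors[3], g), seg(colors[4], g)),    # T15 = fusion(c2,d2)
           rbind(seg(colors[5], g - q), seg(colors[6], q)),   # T16 (e2<->f2)
           rbind(seg(colors[6], g - q), seg(colors[5], q)),   # T17
           rbind(seg(colors[7], g - q), seg(colors[8], q)),   # T18 (g2<->h2)
           rbind(seg(colors[8], g - q), seg(colors[7], q)),   # T19
           rbind(seg(colors[9], g - q), seg(colors[10], q)),  # T20 (i2<->j2)
           rbind(seg(colors[10], g - q), seg(colors[9], q)),  # T21
           seg(colors[11], g), seg(colors[12], g), seg(colors[13], g)))
    names(chroms) <- sprintf("T%02d", seq_len(24L))
    rearr <- data.frame(
      type = c("fusion", "fusion", rep("translocation", 6L)),
      detail = c(paste0("fusion of duplicated ", colors[1], " and ", colors[2]),
                 paste0("fusion of duplicated ", colors[3], " and ", colors[4]),
                 paste0("reciprocal exchange ", colors[5], "<->", colors[6], " (", q, " genes)"),
                 paste0("reciprocal exchange ", colors[6], "<->", colors[5], " (", q, " genes)"),
                 paste0("reciprocal exchange ", colors[7], "<->", colors[8], " (", q, " genes)"),
                 paste0("reciprocal exchange ", colors[8], "<->", colors[7], " (", q, " genes)"),
                 paste0("reciprocal exchange ", colors[9], "<->", colors[10], " (", q, " genes)"),
                 paste0("reciprocal exchange ", colors[10], "<->", colors[9], " (", q, " genes)")),
      stringsAsFactors = FALSE)
    return(ancestor_definition(chroms, name = "teleost_24", colors = colors,
                               rearrangements = rearr))
  }
  # generic layout: 13 singles, then duplicates with colors recycled
  idx <- c(seq_len(13L), rep_len(seq_len(13L), n_chrom))[seq_len(n_chrom)]
  chroms <- lapply(idx, function(i) seg(colors[i], g))
  names(chroms) <- sprintf("T%02d", seq_len(n_chrom))
  ancestor_definition(chroms, name = paste0("teleost_", n_chrom),
                      colors = colors)
}

#' Lay out the genes of an ancestor definition
#'
#' Expands an `ancestor_def` into one row per gene with sequential gene ids,
#' the chromosome id (the label used for painting) and the display color of
#' the segment the gene sits in.
#'
#' @param ancestor An `ancestor_def`.
#' @return Data frame with columns `chromosome`, `index`, `gene_id`,
#'   `display_color`.
#' @export
ancestor_gene_table <- function(ancestor) {
  stopifnot(inherits(ancestor, "ancestor_def"))
  rows <- lapply(names(ancestor$chromosomes), function(cid) {
    segs <- ancestor$chromosomes[[cid]]
    data.frame(chromosome = cid,
               display_color = rep(segs$color, segs$gene_count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$index <- stats::ave(seq_len(nrow(out)), out$chromosome, FUN = seq_along)
  out$gene_id <- sprintf("g%06d", seq_len(nrow(out)))
  out[, c("chromosome", "index", "gene_id", "display_color")]
}

#' Map display colors of an ancestor's chromosomes
#'
#' @param ancestor An `ancestor_def`.
#' @return Named character vector: chromosome id -> dominant display color.
#' @export
ancestor_display_colors <- function(ancestor) {
  stopifnot(inherits(ancestor, "ancestor_def"))
  vapply(ancestor$chromosomes, function(s) {
    s$color[which.max(s$gene_count)]
  }, character(1))
}

#' Write / read an ancestor definition (YAML schema)
#'
#' The schema is shared by hand-written definitions and reconstructed
#' ancestors, so a reconstruction can seed new simulations.
#'
#' @param ancestor An `ancestor_def`.
#' @param path File path.
#' @return `read_ancestor` returns an `ancestor_def`; `write_ancestor`
#'   invisibly returns `path`.
#' @export
write_ancestor <- function(ancestor, path) {
  stopifnot(inherits(ancestor, "ancestor_def"))
  obj <- list(
    name = ancestor$name,
    colors = as.list(ancestor$colors),
    chromosomes = lapply(names(ancestor$chromosomes), function(cid) {
      segs <- ancestor$chromosomes[[cid]]
      list(id = cid,
           segments = lapply(seq_len(nrow(segs)), function(i)
             list(color = segs$color[i], gene_count = segs$gene_count[i])))
    }))
  if (!is.null(ancestor$rearrangements))
    obj$rearrangements <- lapply(seq_len(nrow(ancestor$rearrangements)),
      function(i) as.list(ancestor$rearrangements[i, , drop = FALSE]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ancestor
#' @export
read_ancestor <- function(path) {
  obj <- yaml::read_yaml(path)
  chroms <- lapply(obj$chromosomes, function(ch) {
    do.call(rbind, lapply(ch$segments, function(s)
      data.frame(color = s$color, gene_count = as.integer(s$gene_count),
                 stringsAsFactors = FALSE)))
  })
  names(chroms) <- vapply(obj$chromosomes, `[[`, character(1), "id")
  rearr <- NULL
  if (!is.null(obj$rearrangements))
    rearr <- do.call(rbind, lapply(obj$rearrangements, function(r)
      data.frame(type = r$type, detail = r$detail, stringsAsFactors = FALSE)))
  ancestor_definition(chroms, name = obj$name,
                      colors = unlist(obj$colors), rearrangements = rearr)
}
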