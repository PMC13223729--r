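#' @title Karyotype rendering
#' @description Deterministic SVG ideograms: one bar per chromosome, one
#'   filled rectangle per color block with height proportional to gene
#'   count, and a legend of the 13 proto-chromosome colors. Output is plain
#'   SVG 1.1 text with no timestamps or random ids, so identical input
#'   yields byte-identical files.
#' @name svg
NULL

#' The default 13-color palette (colorblind-aware), keyed a-m
#' @return Named character vector of hex colors.
#' @export
karyotype_palette <- function() {
  c(a = "#332288", b = "#117733", c = "#44AA99", d = "#88CCEE",
    e = "#DDCC77", f = "#CC6677", g = "#AA4499", h = "#882255",
    i = "#6699CC", j = "#661100", k = "#999933", l = "#888888",
    m = "#D55E00")
}

#' Plot geometry and styling for karyotype ideograms
#'
#' @param palette Named fill colors keyed by the 13 letters a-m.
#' @param bar_width,gap Bar width and inter-bar gap in px.
#' @param gene_height Vertical px per gene.
#' @param margin Outer margin in px.
#' @return A `karyotype_plot_spec` list.
#' @export
karyotype_plot_spec <- function(palette = karyotype_palette(),
                                bar_width = 18, gap = 12,
                                gene_height = 0.35, margin = 40) {
  if (anyDuplicated(palette))
    stop("palette must be bijective over the colors in use")
  structure(list(palette = palette, bar_width = bar_width, gap = gap,
                 gene_height = gene_height, margin = margin),
            class = "karyotype_plot_spec")
}

svg_rect <- function(x, y, w, h, fill, stroke = "none", extra = "") {
  sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" stroke="%s"%s/>',
          x, y, w, h, fill, stroke, extra)
}

svg_text <- function(x, y, s, size = 10, anchor = "middle") {
  sprintf('<text x="%.2f" y="%.2f" font-size="%d" font-family="sans-serif" text-anchor="%s">%s</text>',
          x, y, size, anchor, s)
}

#' Render a painted karyotype as SVG
#'
#' @param karyotype A segmented `painted_karyotype` (see [segment_blocks()]).
#' @param spec A [karyotype_plot_spec()].
#' @param path Optional output path; when `NULL` the SVG text is returned.
#' @param ancestor Optional `ancestor_def` used to map painting labels
#'   (ancestral chromosome ids) to their display letters; labels already in
#'   the palette are used directly, and any other label falls back to a
#'   deterministic palette cycle.
#' @return Invisibly (or visibly when `path = NULL`), the SVG document as a
#'   single character string.
#' @export
render_karyotype_svg <- function(karyotype, spec = karyotype_plot_spec(),
                                 path = NULL, ancestor = NULL) {
  stopifnot(inherits(karyotype, "painted_karyotype"))
  if (is.null(karyotype$blocks))
    stop("karyotype must be segmented first (see segment_blocks)")
  blocks <- karyotype$blocks
  pal <- spec$palette
  disp <- if (!is.null(ancestor)) ancestor_display_colors(ancestor) else NULL
  fill_of <- function(label) {
    if (label %in% names(pal)) return(unname(pal[label]))
    if (!is.null(disp) && label %in% names(disp)) {
      d <- disp[[label]]
      if (d %in% names(pal)) return(unname(pal[d]))
    }
    unknown <- sort(setdiff(unique(blocks$color),
                            c(names(pal), names(disp))))
    if (label %in% unknown)
      return(unname(pal[(match(label, unknown) - 1L) %% length(pal) + 1L]))
    stop("unknown color: ", label)
  }
  chroms <- unique(blocks$chromosome)
  m <- spec$margin; bw <- spec$bar_width; gp <- spec$gap
  gh <- spec$gene_height
  heights <- if (nrow(blocks))
    vapply(chroms, function(ch)
      sum(blocks$gene_count[blocks$chromosome == ch]) * gh, numeric(1))
  else numeric(0)
  plot_h <- if (length(heights)) max(heights) else 0
  legend_w <- 90
  width <- m * 2 + max(length(chroms), 1L) * (bw + gp) + legend_w
  height <- m * 2 + max(plot_h, length(pal) * 16)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
                   width, height, width, height),
           sprintf('<title>%s karyotype</title>', karyotype$species))
  x <- m
  for (ch in chroms) {
    b <- blocks[blocks$chromosome == ch, , drop = FALSE]
    total_h <- sum(b$gene_count) * gh
    y <- m
    out <- c(out, sprintf('<g class="chromosome" data-id="%s">', ch))
    out <- c(out, svg_rect(x, y, bw, total_h, "none", stroke = "#333333"))
    for (i in seq_len(nrow(b))) {
      h <- b$gene_count[i] * gh
      out <- c(out, svg_rect(x, y, bw, h, fill_of(b$color[i])))
      y <- y + h
    }
    out <- c(out, svg_text(x + bw / 2, m + total_h + 12, ch, size = 8),
             '</g>')
    x <- x + bw + gp
  }
  # legend: the 13 proto-chromosome colors
  lx <- width - legend_w - m / 2
  out <- c(out, '<g class="legend">')
  for (i in seq_along(pal)) {
    ly <- m + (i - 1L) * 16
    out <- c(out, svg_rect(lx, ly, 12, 12, unname(pal[i])),
             svg_text(lx + 18, ly + 10, names(pal)[i], size = 10,
                      anchor = "start"))
  }
  out <- c(out, '</g>', '</svg>')
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
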