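#' @title Genome-evolution simulator
#' @description Evolves a colored ancestral karyotype along a phylogeny under
#'   a declared event history, emitting painted gene tables per tip and the
#'   ground-truth event log. A karyotype is carried as an ordered list of
#'   chromosomes, each an ordered vector of gene ids; every gene keeps the
#'   ancestral chromosome it descends from as its true color.
#' @name simulator
NULL

# ---- karyotype state helpers -------------------------------------------------

wgd_suffixes <- c("_A", "_B")

# candidate homoeolog suffixes for up to two rounds of duplication
suffix_candidates <- function() {
  one <- wgd_suffixes
  two <- as.vector(outer(one, one, paste0))
  c(one, two)
}

# insert a homoeolog suffix after the base chromosome token of a derived id,
# e.g. transform_id("T10.2", "_A") == "T10_A.2"; fused ids are handled per part
transform_id <- function(id, suffix) {
  if (!nzchar(suffix)) return(id)
  parts <- strsplit(id, "+", fixed = TRUE)[[1]]
  parts <- vapply(parts, function(p) sub("^([^.]+)", paste0("\\1", suffix), p),
                  character(1), USE.NAMES = FALSE)
  paste(parts, collapse = "+")
}

event_operands <- function(ev) {
  switch(ev$type,
    fusion = ev$chromosomes,
    fission = ev$chromosome,
    translocation = c(ev$donor, ev$acceptor),
    complex = event_operands(ev$operations[[1]]))
}

# which suffix groups the event applies under; "" means direct application
resolve_suffix_groups <- function(karyo, ev) {
  ops <- event_operands(ev)
  nm <- names(karyo)
  if (all(ops %in% nm)) return("")
  cand <- suffix_candidates()
  hits <- cand[vapply(cand, function(s)
    all(vapply(ops, transform_id, character(1), suffix = s) %in% nm),
    logical(1))]
  # drop one-round suffixes shadowed by two-round ones (after a second WGD
  # "T01_A" no longer exists, so this is only a tidy-up)
  if (length(hits)) hits else NULL
}

apply_fusion <- function(karyo, a, b) {
  i <- match(a, names(karyo))
  karyo[[i]] <- c(karyo[[a]], karyo[[b]])
  names(karyo)[i] <- paste0(a, "+", b)
  karyo[[b]] <- NULL
  karyo
}

apply_fission <- function(karyo, x, bp) {
  genes <- karyo[[x]]
  n <- length(genes)
  if (bp < 1L || bp >= n)
    stop("fission breakpoint ", bp, " not interior to '", x, "' (", n, " genes)")
  i <- match(x, names(karyo))
  parts <- stats::setNames(list(genes[seq_len(bp)], genes[(bp + 1L):n]),
                           paste0(x, c(".1", ".2")))
  append(karyo[-i], parts, after = i - 1L)
}

apply_translocation <- function(karyo, donor, acceptor, from, to) {
  genes <- karyo[[donor]]
  if (to > length(genes))
    stop("translocated segment [", from, ",", to, "] exceeds '", donor,
         "' (", length(genes), " genes)")
  seg <- genes[from:to]
  karyo[[donor]] <- genes[-(from:to)]
  karyo[[acceptor]] <- c(karyo[[acceptor]], seg)
  if (!length(karyo[[donor]])) karyo[[donor]] <- NULL
  karyo
}

apply_primitive <- function(karyo, ev, suffix) {
  switch(ev$type,
    fusion = apply_fusion(karyo,
                          transform_id(ev$chromosomes[1], suffix),
                          transform_id(ev$chromosomes[2], suffix)),
    fission = apply_fission(karyo, transform_id(ev$chromosome, suffix),
                            ev$breakpoint),
    translocation = apply_translocation(karyo,
                                        transform_id(ev$donor, suffix),
                                        transform_id(ev$acceptor, suffix),
                                        ev$from, ev$to),
    stop("unknown primitive: ", ev$type))
}

apply_wgd <- function(karyo, gene_colors) {
  out <- list()
  for (cid in names(karyo)) {
    ids <- karyo[[cid]]
    a <- paste0(ids, "a"); b <- paste0(ids, "b")
    gene_colors[a] <- gene_colors[ids]
    gene_colors[b] <- gene_colors[ids]
    out[[paste0(cid, "_A")]] <- a
    out[[paste0(cid, "_B")]] <- b
  }
  list(karyo = out, gene_colors = gene_colors)
}

dominant_label <- function(karyo, chrom, gene_colors) {
  tab <- table(gene_colors[karyo[[chrom]]])
  nm <- names(tab)[tab == max(tab)]
  sort(nm)[1]
}

# colors involved in an event, from the dominant labels of its operands at
# application time (first suffix group)
event_colors <- function(karyo, ev, suffix, gene_colors) {
  switch(ev$type,
    fusion = vapply(ev$chromosomes, function(x)
      dominant_label(karyo, transform_id(x, suffix), gene_colors), character(1)),
    fission = dominant_label(karyo, transform_id(ev$chromosome, suffix),
                             gene_colors),
    translocation = c(
      # color of the moved segment, then the acceptor's dominant color
      {
        d <- transform_id(ev$donor, suffix)
        seg <- karyo[[d]][ev$from:ev$to]
        tab <- table(gene_colors[seg]); sort(names(tab)[tab == max(tab)])[1]
      },
      dominant_label(karyo, transform_id(ev$acceptor, suffix), gene_colors)),
    complex = {
      cols <- character(0)
      k <- karyo
      for (op in ev$operations) {
        cols <- c(cols, event_colors(k, op, suffix, gene_colors))
        k <- apply_primitive(k, op, suffix)
      }
      unique(cols)
    })
}

# ---- main entry --------------------------------------------------------------

#' Simulate painted gene tables along a phylogeny
#'
#' Evolves `ancestor` down `scenario$tree`. On each branch a whole-genome
#' duplication (if declared) is applied first, then the branch's events in
#' order; gene loss and mis-coloring are applied independently per gene when
#' a tip's table is emitted. With zero noise, replaying the returned event
#' log from the ancestor reproduces every tip exactly.
#'
#' @param ancestor An `ancestor_def`.
#' @param scenario A `scenario_spec`.
#' @return A `karyo_sim` object: list with
#'   * `tables`: named list (per tip) of data frames with columns `species`,
#'     `chromosome`, `start`, `end`, `gene_id`, `true_color` (the ancestral
#'     chromosome id, `NA` for a lost assignment is never emitted -- lost
#'     genes are dropped);
#'   * `log`: data frame of applied events (`branch`, `index`, `type`,
#'     `colors`, `chromosomes`, `n_copies`);
#'   * `node_chrom_counts`: chromosome count at every node;
#'   * `tip_ploidy`: per-tip expected copies per ancestral chromosome.
#' @export
simulate_karyotypes <- function(ancestor, scenario) {
  stopifnot(inherits(ancestor, "ancestor_def"),
            inherits(scenario, "scenario_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scenario$seed)

  gt <- ancestor_gene_table(ancestor)
  gene_colors <- stats::setNames(gt$chromosome, gt$gene_id)
  root_karyo <- split(gt$gene_id, factor(gt$chromosome,
                                         levels = names(ancestor$chromosomes)))
  labels_all <- node_labels(scenario$tree)
  tree <- scenario$tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L

  states <- vector("list", max(tree$edge))
  states[[root]] <- root_karyo
  node_counts <- stats::setNames(integer(length(labels_all)), labels_all)
  node_counts[labels_all[root]] <- length(root_karyo)

  log_rows <- list()
  # parent-first (preorder) edge traversal
  edges <- ape::reorder.phylo(tree, "cladewise")$edge

  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    bname <- labels_all[child]
    k <- states[[parent]]
    if (bname %in% scenario$wgd_branches) {
      res <- apply_wgd(k, gene_colors)
      k <- res$karyo; gene_colors <- res$gene_colors
    }
    evs <- scenario$events[[bname]]
    for (i in seq_along(evs)) {
      ev <- evs[[i]]
      groups <- resolve_suffix_groups(k, ev)
      if (is.null(groups))
        stop("branch '", bname, "', event ", i, " (", ev$type,
             "): operand chromosome(s) not present at this point: ",
             paste(event_operands(ev), collapse = ", "))
      cols <- event_colors(k, ev, groups[1], gene_colors)
      for (s in groups) {
        if (ev$type == "complex") {
          for (op in ev$operations) k <- apply_primitive(k, op, s)
        } else {
          k <- apply_primitive(k, ev, s)
        }
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        branch = bname, index = i, type = ev$type,
        colors = paste(sort(unique(cols)), collapse = ","),
        chromosomes = paste(event_operands(ev), collapse = ","),
        n_copies = length(groups), stringsAsFactors = FALSE)
    }
    states[[child]] <- k
    node_counts[bname] <- length(k)
  }

  all_labels <- names(ancestor$chromosomes)
  tables <- list()
  tip_ploidy <- stats::setNames(integer(ntip), tree$tip.label)
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    k <- states[[t]]
    nwgd <- sum(path_branches(tree, sp) %in% scenario$wgd_branches)
    tip_ploidy[sp] <- 2L^nwgd
    rows <- lapply(names(k), function(cid) {
      ids <- k[[cid]]
      n <- length(ids)
      data.frame(species = sp, chromosome = cid,
                 start = (seq_len(n) - 1L) * 10000L,
                 end = (seq_len(n) - 1L) * 10000L + 5000L,
                 gene_id = ids,
                 true_color = unname(gene_colors[ids]),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (scenario$loss_rate > 0) {
      keep <- stats::runif(nrow(tab)) >= scenario$loss_rate
      tab <- tab[keep, , drop = FALSE]
    }
    if (scenario$miscolor_rate > 0 && nrow(tab)) {
      flip <- which(stats::runif(nrow(tab)) < scenario$miscolor_rate)
      for (j in flip) {
        others <- setdiff(all_labels, tab$true_color[j])
        tab$true_color[j] <- sample(others, 1L)
      }
    }
    rownames(tab) <- NULL
    tables[[sp]] <- tab
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(branch = character(0), index = integer(0), type = character(0),
               colors = character(0), chromosomes = character(0),
               n_copies = integer(0), stringsAsFactors = FALSE)
  structure(list(tables = tables, log = log,
                 node_chrom_counts = node_counts, tip_ploidy = tip_ploidy,
                 ancestor = ancestor, scenario = scenario),
            class = "karyo_sim")
}

#' @export
print.karyo_sim <- function(x, ...) {
  cat("<karyo_sim> ", x$scenario$name, ": ", length(x$tables), " tips, ",
      nrow(x$log), " logged events\n", sep = "")
  invisible(x)
}

#' Write simulated gene tables to TSV and BED
#'
#' One file per species: `species.genes.tsv` (columns `species`,
#' `chromosome`, `start`, `end`, `gene_id`, `true_color`) and
#' `species.genes.bed` (BED6, 0-based half-open, color in the name field).
#'
#' @param sim A `karyo_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "karyo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in names(sim$tables)) {
    tab <- sim$tables[[sp]]
    tsv <- file.path(dir, paste0(sp, ".genes.tsv"))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    bed <- file.path(dir, paste0(sp, ".genes.bed"))
    gr <- GenomicRanges::GRanges(
      seqnames = tab$chromosome,
      ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
      name = paste0(tab$gene_id, "|", tab$true_color), score = 0L)
    rtracklayer::export(gr, bed, format = "BED")
    paths <- c(paths, tsv, bed)
  }
  invisible(paths)
}
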