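#' @title Rearrangement inference
#' @description Classifies fusion, fission, translocation and complex
#'   rearrangements from the color composition of painted (and, for
#'   tetraploids, collapsed) karyotypes, and places events on a phylogeny by
#'   Dollo parsimony using cross-species signatures.
#' @name inference
NULL

#' Classification thresholds
#'
#' * `min_genes`: a color is *present* on a chromosome when it carries at
#'   least this many genes (reuses the painting filter constant, default 20);
#' * `major_frac`: minimum fraction of a chromosome's colored genes for a
#'   color to count as *major* (default 0.25) -- separates whole-arm fusion
#'   partners from translocated slivers;
#' * `split_frac`: minimum share of a color's genes a carrier must hold to
#'   count toward a fission (default 0.30) -- suppresses noise-driven splits;
#' * `home_frac`: minimum share of a color's genes that must remain on its
#'   home chromosome for a minor occurrence elsewhere to be called a
#'   translocation (default 0.5).
#'
#' @param min_genes,major_frac,split_frac,home_frac See above.
#' @return Named list of thresholds.
#' @export
event_params <- function(min_genes = 20L, major_frac = 0.25,
                         split_frac = 0.30, home_frac = 0.5) {
  stopifnot(min_genes >= 1L, major_frac > 0, major_frac < 1,
            split_frac > 0, split_frac <= 0.5, home_frac > 0, home_frac <= 1)
  list(min_genes = as.integer(min_genes), major_frac = major_frac,
       split_frac = split_frac, home_frac = home_frac)
}

empty_events <- function() {
  data.frame(type = character(0), colors = character(0),
             chromosomes = character(0), donor = character(0),
             acceptor = character(0), signature = character(0),
             stringsAsFactors = FALSE)
}

event_signature <- function(type, colors) {
  paste0(type, ":", vapply(strsplit(colors, ","), function(x)
    paste(sort(x), collapse = ","), character(1)))
}

finish_events <- function(df) {
  if (!nrow(df)) return(empty_events())
  df$signature <- event_signature(df$type, df$colors)
  df <- df[order(df$type, df$colors, df$chromosomes), , drop = FALSE]
  rownames(df) <- NULL
  df
}

as_units_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "ploidy_units")) return(x$composition)
  if (inherits(x, "painted_karyotype")) return(composition_matrix(x))
  stop("cannot interpret input as chromosome/unit compositions")
}

#' Classify rearrangement events from a painted karyotype
#'
#' Applies a deterministic rule set to the per-unit color composition
#' (units are chromosomes for diploid lineages, collapsed homoeolog pairs
#' for post-WGD lineages; see [collapse_wgd()]):
#'
#' 1. **Fusion** -- a unit carries two present colors each with at least
#'    `major_frac` of its colored genes.
#' 2. **Fission** -- a color is present on two or more units each holding at
#'    least `split_frac` of that color's genes.
#' 3. **Translocation** -- a present color with fraction below `major_frac`
#'    on a unit whose majority color differs, while at least `home_frac` of
#'    that color's genes remain on its home unit.
#' 4. **Complex** -- a unit with three or more major colors, or a color
#'    simultaneously satisfying the fusion and fission signatures; the
#'    subsumed primitive calls are absorbed into one complex record
#'    (overlapping complexes sharing a unit or color are merged).
#'
#' Records are returned in canonical order (type, then colors).
#'
#' @param x A `painted_karyotype`, a `ploidy_units` object, or a units-by-
#'   colors count matrix.
#' @param ancestor Optional `ancestor_def`; when given, colors must belong to
#'   its chromosome ids or color universe (unknown colors are an error).
#' @param params Thresholds from [event_params()].
#' @return Data frame of event records with columns `type`, `colors`
#'   (comma-joined, sorted), `chromosomes`, `donor`, `acceptor`, `signature`.
#' @export
classify_events <- function(x, ancestor = NULL, params = event_params()) {
  M <- as_units_matrix(x)
  if (!is.null(ancestor)) {
    ok <- c(names(ancestor$chromosomes), ancestor$colors)
    unknown <- setdiff(colnames(M), ok)
    if (length(unknown))
      stop("unknown color(s) not in the ancestor definition: ",
           paste(unknown, collapse = ", "))
  }
  if (!nrow(M) || !ncol(M)) return(empty_events())
  if (any(M > 0 & M < params$min_genes)) {
    warning("unfiltered karyotype: colors below min_genes present; ",
            "auto-filtering")
    M[M < params$min_genes] <- 0L
  }
  storage.mode(M) <- "double"
  rs <- rowSums(M)
  cs <- colSums(M)
  present <- M >= params$min_genes
  rf <- M / ifelse(rs > 0, rs, 1)
  cf <- sweep(M, 2L, ifelse(cs > 0, cs, 1), "/")
  major <- present & rf >= params$major_frac
  units <- rownames(M) %||% paste0("u", seq_len(nrow(M)))
  cols <- colnames(M)

  # majority color per unit (ties -> first column)
  maj_col <- apply(M, 1L, function(r) if (all(r == 0)) NA_integer_ else
    which.max(r))

  # -- candidate fissions: colors with >= 2 strong carriers
  fiss_carriers <- present & cf >= params$split_frac
  fiss_colors <- cols[colSums(fiss_carriers) >= 2L]

  # -- candidate fusions: units with >= 2 major colors
  fus_units <- which(rowSums(major) >= 2L)

  # -- candidate translocations
  trans <- list()
  home <- apply(M, 2L, which.max)  # unit index holding most of each color
  for (ci in seq_along(cols)) {
    hold <- cf[home[ci], ci]
    if (hold < params$home_frac) next
    for (ui in which(present[, ci] & rf[, ci] < params$major_frac)) {
      if (ui == home[ci]) next
      mc <- maj_col[ui]
      if (is.na(mc) || mc == ci) next
      trans[[length(trans) + 1L]] <- data.frame(
        type = "translocation",
        colors = paste(sort(c(cols[ci], cols[mc])), collapse = ","),
        chromosomes = paste(sort(c(units[ui], units[home[ci]])), collapse = ","),
        donor = cols[ci], acceptor = cols[mc], stringsAsFactors = FALSE)
    }
  }

  # -- complex seeds
  seeds <- list()  # each: list(units = int vec, colors = chr vec)
  for (ui in fus_units) {
    if (sum(major[ui, ]) >= 3L)
      seeds[[length(seeds) + 1L]] <- list(units = ui,
                                          colors = cols[major[ui, ]])
  }
  for (cc in fiss_colors) {
    ci <- match(cc, cols)
    fus_with <- which(major[, ci] & rowSums(major) >= 2L)
    if (length(fus_with)) {
      involved <- unique(unlist(lapply(fus_with, function(u) cols[major[u, ]])))
      seeds[[length(seeds) + 1L]] <-
        list(units = unique(c(fus_with, which(fiss_carriers[, ci]))),
             colors = unique(c(cc, involved)))
    }
  }
  # merge seeds sharing a unit or color
  merged <- list()
  for (s in seeds) {
    hit <- which(vapply(merged, function(m)
      length(intersect(m$units, s$units)) > 0L ||
        length(intersect(m$colors, s$colors)) > 0L, logical(1)))
    if (length(hit)) {
      keep <- merged[-hit]
      joined <- s
      for (h in hit) {
        joined$units <- union(joined$units, merged[[h]]$units)
        joined$colors <- union(joined$colors, merged[[h]]$colors)
      }
      merged <- c(keep, list(joined))
    } else merged <- c(merged, list(s))
  }
  cx_units <- unique(unlist(lapply(merged, `[[`, "units")))
  cx_colors <- unique(unlist(lapply(merged, `[[`, "colors")))

  rows <- list()
  for (m in merged)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "complex", colors = paste(sort(m$colors), collapse = ","),
      chromosomes = paste(sort(units[m$units]), collapse = ","),
      donor = NA_character_, acceptor = NA_character_,
      stringsAsFactors = FALSE)
  for (ui in setdiff(fus_units, cx_units)) {
    mc <- cols[major[ui, ]]
    pairs <- utils::combn(sort(mc), 2L)
    for (j in seq_len(ncol(pairs)))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "fusion", colors = paste(pairs[, j], collapse = ","),
        chromosomes = units[ui], donor = NA_character_,
        acceptor = NA_character_, stringsAsFactors = FALSE)
  }
  for (cc in setdiff(fiss_colors, cx_colors)) {
    ci <- match(cc, cols)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "fission", colors = cc,
      chromosomes = paste(sort(units[fiss_carriers[, ci]]), collapse = ","),
      donor = NA_character_, acceptor = NA_character_,
      stringsAsFactors = FALSE)
  }
  rows <- c(rows, trans)
  finish_events(if (length(rows)) do.call(rbind, rows) else empty_events())
}

#' Place classified events on a phylogeny (Dollo parsimony)
#'
#' An event signature shared by every sampled descendant of a node and
#' absent outside that clade is assigned once to the node's stem branch (the
#' deepest consistent branch). Signatures carried by a non-clade species set
#' are assigned independently to each maximal clade in which they are
#' universally present. The output partitions all distinct input signatures.
#'
#' @param per_species_events Named list: species -> event records (from
#'   [classify_events()]).
#' @param tree An [ape::phylo] covering all species (extra tips allowed;
#'   they count as signature-absent).
#' @return Data frame of placed events: `branch`, `type`, `colors`,
#'   `signature`, `n_species`.
#' @export
place_on_tree <- function(per_species_events, tree) {
  if (!inherits(tree, "phylo")) tree <- read_tree(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree <- read_tree(ape::write.tree(tree))
  sp <- names(per_species_events)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  labs <- node_labels(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  # carriers per signature
  sigs <- list()
  for (s in sp) {
    ev <- per_species_events[[s]]
    if (is.null(ev) || !nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      key <- ev$signature[i]
      if (is.null(sigs[[key]]))
        sigs[[key]] <- list(row = ev[i, c("type", "colors"), drop = FALSE],
                            carriers = character(0))
      sigs[[key]]$carriers <- union(sigs[[key]]$carriers, s)
    }
  }
  if (!length(sigs)) return(data.frame(branch = character(0),
    type = character(0), colors = character(0), signature = character(0),
    n_species = integer(0), stringsAsFactors = FALSE))
  # tip sets per node
  nodes <- seq_len(ntip + tree$Nnode)
  tipsets <- lapply(nodes, clade_tips, tree = tree)
  parent <- integer(max(nodes))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rows <- list()
  for (key in sort(names(sigs))) {
    S <- sigs[[key]]$carriers
    inside <- vapply(tipsets, function(ts) all(ts %in% S), logical(1))
    maximal <- which(inside & vapply(nodes, function(n)
      n == root || !inside[parent[n]], logical(1)))
    for (n in maximal) {
      # a signature carried by every sampled species has no stem branch to
      # sit on; it is reported once under the root's label
      rows[[length(rows) + 1L]] <- data.frame(
        branch = labs[n], type = sigs[[key]]$row$type,
        colors = sigs[[key]]$row$colors, signature = key,
        n_species = length(S), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$branch, out$type, out$colors), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize placed events per branch
#'
#' @param branch_events Data frame from [place_on_tree()].
#' @param tree Optional tree; when given, every branch appears (zero counts
#'   included) in traversal order.
#' @return Data frame: `branch`, `fusion`, `fission`, `translocation`,
#'   `complex`, `total`.
#' @export
summarize_events <- function(branch_events, tree = NULL) {
  types <- c("fusion", "fission", "translocation", "complex")
  branches <- if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) tree <- read_tree(tree)
    union(branch_labels(tree), unique(branch_events$branch))
  } else sort(unique(branch_events$branch))
  out <- data.frame(branch = branches, stringsAsFactors = FALSE)
  for (tp in types)
    out[[tp]] <- vapply(branches, function(b)
      sum(branch_events$branch == b & branch_events$type == tp), integer(1))
  out$total <- rowSums(out[, types, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write / read an event report (JSON)
#'
#' @param branch_events Data frame of placed events.
#' @param path File path.
#' @return `read_events_json` returns the data frame; `write_events_json`
#'   invisibly returns `path`.
#' @export
write_events_json <- function(branch_events, path) {
  jsonlite::write_json(branch_events, path, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  out <- jsonlite::fromJSON(path)
  as.data.frame(out, stringsAsFactors = FALSE)
}
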