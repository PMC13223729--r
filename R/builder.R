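#' @title Ancestral karyotype reconstruction
#' @description Collapses WGD-derived homoeologous chromosomes into ploidy
#'   units and reconstructs the ancestral karyotype shared by the sampled
#'   species from the units' major-color compositions.
#' @name builder
NULL

cosine_sim <- function(M) {
  n <- sqrt(rowSums(M^2))
  n[n == 0] <- 1
  S <- (M %*% t(M)) / outer(n, n)
  S
}

greedy_pair <- function(M, min_similarity) {
  n <- nrow(M)
  if (n < 2L) return(list(pairs = matrix(integer(0), ncol = 2), single = seq_len(n)))
  S <- cosine_sim(M)
  diag(S) <- -Inf
  S[lower.tri(S)] <- -Inf
  avail <- rep(TRUE, n)
  pairs <- list()
  repeat {
    S2 <- S
    S2[!avail, ] <- -Inf
    S2[, !avail] <- -Inf
    best <- which.max(S2)
    if (!length(best) || S2[best] < min_similarity) break
    ij <- arrayInd(best, dim(S2))
    pairs[[length(pairs) + 1L]] <- c(ij[1], ij[2])
    avail[ij] <- FALSE
    if (sum(avail) < 2L) break
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(integer(0), ncol = 2),
       single = which(avail))
}

#' Collapse homoeologous chromosomes into ploidy units
#'
#' For a post-WGD karyotype (`ploidy > 1`), chromosomes are paired by greedy
#' maximum cosine similarity of their color-composition vectors (highest
#' remaining similarity first); unpaired leftovers become singleton units.
#' Unit compositions are the summed counts of their members. Diploid
#' karyotypes pass through unchanged. A ploidy-4 karyotype is collapsed in
#' two rounds.
#'
#' @param karyotype A `painted_karyotype` (its `ploidy` drives the number of
#'   collapse rounds).
#' @param min_similarity Minimum cosine similarity for a pairing
#'   (default 0.2); chromosomes with no partner above it stay singletons.
#' @return An object of class `ploidy_units`: list with `species`, `ploidy`,
#'   `composition` (units-by-colors count matrix) and `members` (list of
#'   member chromosome ids per unit).
#' @export
collapse_wgd <- function(karyotype, min_similarity = 0.2) {
  stopifnot(inherits(karyotype, "painted_karyotype"))
  M <- composition_matrix(karyotype)
  members <- as.list(rownames(M))
  rounds <- as.integer(log2(karyotype$ploidy))
  for (r in seq_len(rounds)) {
    if (nrow(M) < 2L) break
    gp <- greedy_pair(M, min_similarity)
    comp <- list(); memb <- list()
    if (nrow(gp$pairs)) for (p in seq_len(nrow(gp$pairs))) {
      i <- gp$pairs[p, 1]; j <- gp$pairs[p, 2]
      comp[[length(comp) + 1L]] <- M[i, ] + M[j, ]
      memb[[length(memb) + 1L]] <- c(members[[i]], members[[j]])
    }
    for (i in gp$single) {
      comp[[length(comp) + 1L]] <- M[i, ]
      memb[[length(memb) + 1L]] <- members[[i]]
    }
    M2 <- do.call(rbind, comp)
    rownames(M2) <- vapply(memb, function(m) paste(sort(m), collapse = "|"),
                           character(1))
    o <- order(rownames(M2))
    M <- M2[o, , drop = FALSE]
    members <- memb[o]
  }
  structure(list(species = karyotype$species, ploidy = karyotype$ploidy,
                 composition = M, members = members),
            class = "ploidy_units")
}

#' @export
print.ploidy_units <- function(x, ...) {
  cat("<ploidy_units> ", x$species, ": ", nrow(x$composition),
      " units (ploidy ", x$ploidy, ")\n", sep = "")
  invisible(x)
}

unit_major_sets <- function(units, params) {
  M <- units$composition
  rs <- rowSums(M)
  out <- vector("list", nrow(M))
  for (i in seq_len(nrow(M))) {
    if (rs[i] == 0) { out[[i]] <- character(0); next }
    frac <- M[i, ] / rs[i]
    out[[i]] <- sort(colnames(M)[M[i, ] >= params$min_genes &
                                   frac >= params$major_frac])
  }
  out
}

#' Reconstruct the ingroup's ancestral karyotype
#'
#' Candidate ancestral chromosomes are the distinct major-color compositions
#' of the species' ploidy units. A candidate copy enters the ancestor when
#' the species carrying it either span at least two child clades of the
#' ingroup root -- so Dollo parsimony (derived states arise once, losses
#' allowed) implies presence at the root -- or make up at least `quorum` of
#' the ingroup. Copy numbers are handled per signature: a second copy of the
#' same major-color set is admitted only if the species carrying two such
#' units themselves satisfy the rule, and so on.
#'
#' @param collapsed Named list: species -> `ploidy_units`.
#' @param tree Phylogeny covering the species.
#' @param quorum Required support fraction in `(0.5, 1]` (default 0.75).
#' @param outgroup Optional tip label(s) excluded from the ingroup.
#' @param params Thresholds from [event_params()] (`min_genes`,
#'   `major_frac` delimit major colors).
#' @return An object of class `reconstructed_ancestor`: list with
#'   `chromosomes` (named list of per-color gene-count vectors, ordered by
#'   size), `support` (data frame: `chromosome`, `major_colors`, `copy`,
#'   `n_species`, `species`), `quorum`.
#' @export
reconstruct_ancestor <- function(collapsed, tree, quorum = 0.75,
                                 outgroup = NULL, params = event_params()) {
  if (!inherits(tree, "phylo")) tree <- read_tree(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree <- read_tree(ape::write.tree(tree))
  if (quorum <= 0.5 || quorum > 1)
    stop("quorum must be in (0.5, 1]: an ambiguous majority is rejected")
  sp <- names(collapsed)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  ingroup <- setdiff(sp, outgroup)
  if (length(ingroup) < 2L)
    stop("reconstruction needs at least 2 ingroup species")
  # ingroup root and its child clades
  ing_nodes <- match(ingroup, tree$tip.label)
  mrca <- if (length(ing_nodes) == ape::Ntip(tree)) ape::Ntip(tree) + 1L else
    ape::getMRCA(tree, ingroup)
  kids <- tree$edge[tree$edge[, 1] == mrca, 2]
  kid_tips <- lapply(kids, clade_tips, tree = tree)

  # per species: signature -> count and matching unit compositions
  sig_data <- list()
  for (s in ingroup) {
    units <- collapsed[[s]]
    majors <- unit_major_sets(units, params)
    for (i in seq_along(majors)) {
      if (!length(majors[[i]])) next
      key <- paste(majors[[i]], collapse = ",")
      if (is.null(sig_data[[key]]))
        sig_data[[key]] <- list()
      sig_data[[key]][[s]] <- c(sig_data[[key]][[s]],
                                list(units$composition[i, ] / units$ploidy))
    }
  }
  if (!length(sig_data)) stop("no major-color compositions to reconstruct from")

  admits <- function(carriers) {
    if (length(carriers) / length(ingroup) >= quorum) return(TRUE)
    spans <- sum(vapply(kid_tips, function(ts)
      any(carriers %in% ts), logical(1)))
    spans >= 2L
  }

  chroms <- list(); support <- list()
  for (key in sort(names(sig_data))) {
    per_sp <- sig_data[[key]]
    counts <- lengths(per_sp)
    m <- 1L
    repeat {
      carriers <- names(counts)[counts >= m]
      if (!length(carriers) || !admits(carriers)) break
      # copy m: average the m-th largest matching unit across carriers
      comps <- lapply(carriers, function(s) {
        u <- per_sp[[s]]
        sizes <- vapply(u, sum, numeric(1))
        u[[order(-sizes)[m]]]
      })
      comp <- Reduce(`+`, comps) / length(comps)
      comp <- round(comp[comp > 0])
      comp <- comp[comp > 0]
      chroms[[length(chroms) + 1L]] <- comp
      support[[length(support) + 1L]] <- data.frame(
        major_colors = key, copy = m, n_species = length(carriers),
        species = paste(sort(carriers), collapse = ","),
        stringsAsFactors = FALSE)
      m <- m + 1L
    }
  }
  if (!length(chroms)) stop("no candidate met the support rule")
  sizes <- vapply(chroms, sum, numeric(1))
  o <- order(-sizes, vapply(support, `[[`, character(1), "major_colors"))
  chroms <- chroms[o]
  supp <- do.call(rbind, support)[o, , drop = FALSE]
  names(chroms) <- sprintf("A%02d", seq_along(chroms))
  supp <- cbind(data.frame(chromosome = names(chroms),
                           stringsAsFactors = FALSE), supp)
  rownames(supp) <- NULL
  structure(list(chromosomes = chroms, support = supp, quorum = quorum),
            class = "reconstructed_ancestor")
}

#' @export
print.reconstructed_ancestor <- function(x, ...) {
  cat("<reconstructed_ancestor> ", length(x$chromosomes),
      " chromosomes (quorum ", x$quorum, ")\n", sep = "")
  invisible(x)
}

#' Convert a reconstruction to an ancestor definition
#'
#' The reconstructed chromosomes are re-expressed in the shared ancestor
#' schema so they can seed new simulations; the color universe becomes the
#' set of paint labels observed.
#'
#' @param rec A `reconstructed_ancestor`.
#' @param name Definition label.
#' @return An `ancestor_def`.
#' @export
as_ancestor_def <- function(rec, name = "reconstructed") {
  stopifnot(inherits(rec, "reconstructed_ancestor"))
  labels <- sort(unique(unlist(lapply(rec$chromosomes, names))))
  chroms <- lapply(rec$chromosomes, function(comp)
    data.frame(color = names(comp), gene_count = as.integer(comp),
               stringsAsFactors = FALSE))
  # 13-symbol invariant only binds the teleost universe; reconstructed
  # definitions carry their own label set
  ancestor_definition(chroms, name = name, colors = labels)
}

#' Write the reconstruction's support table
#' @param rec A `reconstructed_ancestor`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_support_table <- function(rec, path) {
  utils::write.table(rec$support, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
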