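#' @title Evolutionary scenarios for the karyotype simulator
#' @description A scenario couples a rooted phylogeny with an ordered event
#'   history per branch (fusions, fissions, translocations, complex
#'   composites), the set of branches carrying a whole-genome duplication,
#'   and the noise model (per-gene loss and mis-coloring rates).
#' @name scenario
NULL

#' Event specifications
#'
#' Constructors for the four rearrangement primitives understood by the
#' simulator. Breakpoints and segment bounds are 1-based gene indices on the
#' chromosome at the time the event applies. A complex event is an atomic
#' composition of two or more primitives.
#'
#' On branches below a whole-genome duplication, operand ids may name the
#' pre-duplication chromosome; the event is then applied mirrored to every
#' homoeologous copy and logged once.
#'
#' @param a,b Chromosome ids to fuse (in order; `a`'s genes come first).
#' @param chromosome Chromosome id to split.
#' @param breakpoint Interior gene index: genes `1..breakpoint` form the first
#'   product, the rest the second.
#' @param donor,acceptor Chromosome ids for a translocation.
#' @param from,to 1-based bounds of the donor segment (appended to the
#'   acceptor's end).
#' @param ... For `ev_complex`, two or more primitive event specs.
#' @return An object of class `event_spec`.
#' @export
ev_fusion <- function(a, b) {
  stopifnot(is.character(a), is.character(b), a != b)
  structure(list(type = "fusion", chromosomes = c(a, b)), class = "event_spec")
}

#' @rdname ev_fusion
#' @export
ev_fission <- function(chromosome, breakpoint) {
  breakpoint <- as.integer(breakpoint)
  stopifnot(is.character(chromosome), breakpoint >= 1L)
  structure(list(type = "fission", chromosome = chromosome,
                 breakpoint = breakpoint), class = "event_spec")
}

#' @rdname ev_fusion
#' @export
ev_translocation <- function(donor, acceptor, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(is.character(donor), is.character(acceptor), donor != acceptor,
            from >= 1L, to >= from)
  structure(list(type = "translocation", donor = donor, acceptor = acceptor,
                 from = from, to = to), class = "event_spec")
}

#' @rdname ev_fusion
#' @export
ev_complex <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && !inherits(ops[[1]], "event_spec"))
    ops <- ops[[1]]
  if (length(ops) < 2L)
    stop("a complex event composes >= 2 primitive operations")
  if (!all(vapply(ops, inherits, logical(1), "event_spec")))
    stop("complex operations must be event specs")
  if (any(vapply(ops, function(o) o$type, character(1)) == "complex"))
    stop("complex events cannot nest")
  structure(list(type = "complex", operations = ops), class = "event_spec")
}

#' Construct a simulation scenario
#'
#' @param tree A rooted phylogeny: an [ape::phylo], a Newick string, or a path
#'   to a Newick file. Branches are addressed by the label of the node at
#'   their child end.
#' @param events Named list: branch label -> ordered list of `event_spec`s.
#' @param wgd_branches Branch labels carrying a whole-genome duplication
#'   (applied before that branch's events).
#' @param genes_per_segment Marker density used when the paired ancestor is
#'   built from this scenario (informational; the ancestor object governs).
#' @param loss_rate Per-gene retention failure probability in `[0, 1]`,
#'   applied at the tips after all structural events.
#' @param miscolor_rate Per-gene probability of random color reassignment in
#'   `[0, 1]`, applied at the tips.
#' @param seed Integer seed; a fixed seed makes the simulation byte-identical.
#' @param outgroup Optional tip label treated as outgroup by downstream
#'   reconstruction.
#' @param name Scenario label.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(tree, events = list(), wgd_branches = character(),
                          genes_per_segment = 400L, loss_rate = 0,
                          miscolor_rate = 0, seed = 1L, outgroup = NULL,
                          name = "scenario") {
  if (!inherits(tree, "phylo")) tree <- read_tree(tree)
  else {
    if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
      tree <- read_tree(ape::write.tree(tree))
  }
  if (loss_rate < 0 || loss_rate > 1) stop("loss_rate must be in [0, 1]")
  if (miscolor_rate < 0 || miscolor_rate > 1)
    stop("miscolor_rate must be in [0, 1]")
  branches <- branch_labels(tree)
  if (length(events)) {
    if (is.null(names(events)) || any(!nzchar(names(events))))
      stop("'events' must be a named list keyed by branch label")
    bad <- setdiff(names(events), branches)
    if (length(bad))
      stop("event branches not in tree: ", paste(bad, collapse = ", "))
    for (b in names(events))
      if (!all(vapply(events[[b]], inherits, logical(1), "event_spec")))
        stop("events for branch '", b, "' must be event specs")
  }
  bad <- setdiff(wgd_branches, branches)
  if (length(bad))
    stop("WGD branches not in tree: ", paste(bad, collapse = ", "))
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label)
    stop("outgroup not a tip of the tree: ", outgroup)
  structure(list(tree = tree, events = events, wgd_branches = wgd_branches,
                 genes_per_segment = as.integer(genes_per_segment),
                 loss_rate = loss_rate, miscolor_rate = miscolor_rate,
                 seed = as.integer(seed), outgroup = outgroup, name = name),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, ": ", ape::Ntip(x$tree), " tips, ",
      sum(lengths(x$events)), " events on ", length(x$events), " branches, ",
      length(x$wgd_branches), " WGD branch(es)\n", sep = "")
  invisible(x)
}

#' The packaged Cypriniformes evolution scenario
#'
#' The canonical study design: a 24-chromosome teleost ancestor evolves along
#' an 8-taxon tree (7 cypriniforms, medaka outgroup). The Cypriniformes stem
#' carries 9 rearrangements -- 2 fusions, 1 fission, 4 translocations and 2
#' complex events -- producing a 25-chromosome cypriniform ancestor. Grass
#' carp carries one terminal fusion; rare minnow and zebrafish are unchanged;
#' the carp lineage (purse red carp and both koi variants) carries a
#' whole-genome duplication with one small fusion on the koi stem; the
#' *Sinocyclocheilus* lineage carries its own duplication followed by 2
#' fusions and 2 fissions.
#'
#' The stem-event operands are a concrete choice consistent with the declared
#' event-type counts; they are recorded here (and in the shipped scenario
#' file) rather than asserted to match any particular published breakpoint.
#'
#' @param genes_per_segment Marker density per color segment (default 400).
#' @param seed Simulation seed (default 1).
#' @param loss_rate,miscolor_rate Noise rates (default 0).
#' @return List with elements `ancestor` (an `ancestor_def`) and `scenario`
#'   (a `scenario_spec`).
#' @export
cypriniformes_scenario <- function(genes_per_segment = 400L, seed = 1L,
                                   loss_rate = 0, miscolor_rate = 0) {
  g <- as.integer(genes_per_segment)
  anc <- build_teleost_ancestor(24L, genes_per_segment = g)
  bp <- as.integer(round(0.6 * g))               # 60/40 fission split
  sl <- max(21L, as.integer(round(0.15 * g)))    # translocated sliver
  fr <- as.integer(round(0.45 * g))
  to <- fr + sl - 1L
  newick <- paste0(
    "(((zebrafish,rare_minnow)danionidae,(grass_carp,((purse_red_carp,",
    "(koi_black,koi_golden)koi)cyprinus,sinocyclocheilus)cyprininae)",
    "cyprinidae)cypriniformes,medaka)root;")
  events <- list(
    cypriniformes = list(
      ev_fusion("T16", "T17"),
      ev_fusion("T18", "T19"),
      ev_fission("T01", bp),
      ev_translocation("T02", "T03", fr, to),
      ev_translocation("T04", "T05", fr, to),
      ev_translocation("T06", "T07", fr, to),
      ev_translocation("T08", "T09", fr, to),
      ev_complex(ev_fission("T10", bp), ev_fission("T11", bp),
                 ev_fusion("T10.2", "T11.2")),
      ev_complex(ev_fission("T12", bp), ev_fission("T13", bp),
                 ev_fusion("T12.2", "T13.2"))),
    grass_carp = list(ev_fusion("T20", "T21")),
    koi = list(ev_fusion("T22", "T23")),
    sinocyclocheilus = list(
      ev_fusion("T14", "T15"),
      ev_fusion("T24", "T20"),
      ev_fission("T21", bp),
      ev_fission("T22", bp)))
  sc <- scenario_spec(newick, events = events,
                      wgd_branches = c("cyprinus", "sinocyclocheilus"),
                      genes_per_segment = g, loss_rate = loss_rate,
                      miscolor_rate = miscolor_rate, seed = seed,
                      outgroup = "medaka", name = "cypriniformes_fig")
  list(ancestor = anc, scenario = sc)
}

event_to_record <- function(ev) {
  switch(ev$type,
    fusion = list(type = "fusion", chromosomes = as.list(ev$chromosomes)),
    fission = list(type = "fission", chromosome = ev$chromosome,
                   breakpoint = ev$breakpoint),
    translocation = list(type = "translocation", donor = ev$donor,
                         acceptor = ev$acceptor, from = ev$from, to = ev$to),
    complex = list(type = "complex",
                   operations = lapply(ev$operations, event_to_record)))
}

record_to_event <- function(r) {
  switch(r$type,
    fusion = ev_fusion(r$chromosomes[[1]], r$chromosomes[[2]]),
    fission = ev_fission(r$chromosome, r$breakpoint),
    translocation = ev_translocation(r$donor, r$acceptor, r$from, r$to),
    complex = ev_complex(lapply(r$operations, record_to_event)),
    stop("unknown event type in scenario file: ", r$type))
}

#' Write / read a scenario (YAML schema)
#'
#' The schema stores the tree as a Newick string, events as typed records,
#' WGD branch labels and the noise parameters; `read_scenario` restores a
#' `scenario_spec` equal to the one written.
#'
#' @param scenario A `scenario_spec`.
#' @param path File path.
#' @return `read_scenario` returns a `scenario_spec`; `write_scenario`
#'   invisibly returns `path`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  obj <- list(
    name = scenario$name,
    tree = ape::write.tree(scenario$tree),
    wgd_branches = as.list(scenario$wgd_branches),
    genes_per_segment = scenario$genes_per_segment,
    loss_rate = scenario$loss_rate,
    miscolor_rate = scenario$miscolor_rate,
    seed = scenario$seed,
    events = lapply(scenario$events, function(evs)
      lapply(evs, event_to_record)))
  if (!is.null(scenario$outgroup)) obj$outgroup <- scenario$outgroup
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  events <- lapply(obj$events, function(evs) lapply(evs, record_to_event))
  scenario_spec(obj$tree, events = events,
                wgd_branches = unlist(obj$wgd_branches) %||% character(0),
                genes_per_segment = obj$genes_per_segment,
                loss_rate = obj$loss_rate, miscolor_rate = obj$miscolor_rate,
                seed = obj$seed, outgroup = obj$outgroup, name = obj$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a random recoverable scenario
#'
#' Generates a random tree and a random event history in which every event
#' operates on chromosomes untouched anywhere else in the history, with
#' breakpoints and segment sizes chosen inside the classifier's detection
#' envelope. Used for seeded round-trip validation of the inference rules.
#'
#' @param seed Integer seed (the generator restores the RNG state on exit).
#' @param n_tips Number of tips (>= 3).
#' @param n_chrom Ancestor chromosome count.
#' @param genes_per_segment Marker density.
#' @param max_events_per_branch Upper bound on events drawn per branch.
#' @param wgd_prob Probability that one randomly chosen branch carries a WGD.
#' @param loss_rate,miscolor_rate Noise rates passed to the scenario.
#' @return List with elements `ancestor` and `scenario`.
#' @export
random_scenario <- function(seed, n_tips = 4L, n_chrom = 18L,
                            genes_per_segment = 120L,
                            max_events_per_branch = 2L, wgd_prob = 0.3,
                            loss_rate = 0, miscolor_rate = 0) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  g <- as.integer(genes_per_segment)
  anc <- build_teleost_ancestor(n_chrom, genes_per_segment = g)
  tr <- ape::rtree(n_tips, tip.label = paste0("sp", seq_len(n_tips)))
  tr$edge.length <- NULL
  tr <- read_tree(ape::write.tree(tr))
  branches <- branch_labels(tr)
  pool <- sample(names(anc$chromosomes))
  take <- function(k) {
    if (length(pool) < k) return(NULL)
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  bp <- as.integer(round(0.6 * g))
  sl <- max(24L, as.integer(round(0.2 * g)))
  fr <- as.integer(round(0.4 * g)); to <- fr + sl - 1L
  events <- list()
  for (b in branches) {
    k <- sample(0:max_events_per_branch, 1L)
    evs <- list()
    for (i in seq_len(k)) {
      type <- sample(c("fusion", "fission", "translocation", "complex"), 1L)
      ev <- switch(type,
        fusion = { cc <- take(2L); if (is.null(cc)) NULL else ev_fusion(cc[1], cc[2]) },
        fission = { cc <- take(1L); if (is.null(cc)) NULL else ev_fission(cc, bp) },
        translocation = { cc <- take(2L); if (is.null(cc)) NULL
                          else ev_translocation(cc[1], cc[2], fr, to) },
        complex = { cc <- take(2L); if (is.null(cc)) NULL
                    else ev_complex(ev_fission(cc[1], bp), ev_fission(cc[2], bp),
                                    ev_fusion(paste0(cc[1], ".2"),
                                              paste0(cc[2], ".2"))) })
      if (is.null(ev)) break
      evs <- c(evs, list(ev))
    }
    if (length(evs)) events[[b]] <- evs
  }
  wgd <- character(0)
  if (stats::runif(1) < wgd_prob) wgd <- sample(branches, 1L)
  sc <- scenario_spec(tr, events = events, wgd_branches = wgd,
                      genes_per_segment = g, loss_rate = loss_rate,
                      miscolor_rate = miscolor_rate, seed = as.integer(seed),
                      name = paste0("random_", seed))
  list(ancestor = anc, scenario = sc)
}
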