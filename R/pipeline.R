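#' @title End-to-end pipeline
#' @description Convenience driver chaining simulate (or user tables) ->
#'   paint -> filter -> segment -> collapse -> classify -> place ->
#'   summarize -> reconstruct, as used for scenario validation.
#' @name pipeline
NULL

#' Run the painting and inference pipeline on a simulated scenario
#'
#' Simulates the scenario, paints every tip directly from the emitted color
#' assignments, applies the minimum-count filter and block segmentation,
#' collapses homoeologs on post-WGD lineages, classifies events per species
#' against the ancestor, places them on the tree by Dollo parsimony, and
#' (when at least two ingroup species exist) reconstructs the ingroup's
#' ancestral karyotype.
#'
#' @param ancestor An `ancestor_def`.
#' @param scenario A `scenario_spec`.
#' @param params Thresholds from [event_params()].
#' @param smoothing_window Odd block-smoothing window (default 1).
#' @param quorum Reconstruction support fraction (default 0.75).
#' @param outgroup Outgroup tip label (default: the scenario's).
#' @param reconstruct Whether to attempt reconstruction (default `TRUE` when
#'   an outgroup leaves >= 2 ingroup species).
#' @return List with `sim`, `painted` (per species), `collapsed` (per
#'   species `ploidy_units`), `events` (per species), `placed`, `summary`
#'   and `reconstruction` (`NULL` when skipped).
#' @export
run_scenario_pipeline <- function(ancestor, scenario, params = event_params(),
                                  smoothing_window = 1L, quorum = 0.75,
                                  outgroup = scenario$outgroup,
                                  reconstruct = NULL) {
  sim <- simulate_karyotypes(ancestor, scenario)
  painted <- list(); collapsed <- list(); events <- list()
  for (sp in names(sim$tables)) {
    pk <- painted_karyotype(sim$tables[[sp]], species = sp,
                            ploidy = sim$tip_ploidy[[sp]])
    pk <- filter_minor_colors(pk, params$min_genes)
    pk <- segment_blocks(pk, smoothing_window)
    painted[[sp]] <- pk
    units <- collapse_wgd(pk)
    collapsed[[sp]] <- units
    events[[sp]] <- classify_events(units, ancestor = ancestor,
                                    params = params)
  }
  placed <- place_on_tree(events, scenario$tree)
  summ <- summarize_events(placed, scenario$tree)
  do_rec <- reconstruct %||%
    (length(setdiff(names(sim$tables), outgroup)) >= 2L)
  rec <- if (isTRUE(do_rec)) {
    reconstruct_ancestor(collapsed[setdiff(names(collapsed), outgroup)],
                         scenario$tree, quorum = quorum,
                         outgroup = outgroup, params = params)
  } else NULL
  list(sim = sim, painted = painted, collapsed = collapsed, events = events,
       placed = placed, summary = summ, reconstruction = rec)
}

# signature multiset per branch from a true event log
log_signatures <- function(log) {
  if (!nrow(log)) return(list())
  split(event_signature(log$type, log$colors), log$branch)
}

# signature multiset per branch from placed events
placed_signatures <- function(placed) {
  if (!nrow(placed)) return(list())
  split(placed$signature, placed$branch)
}

#' Compare a true event log with placed inferences
#'
#' @param log True event log (from a `karyo_sim`).
#' @param placed Placed events (from [place_on_tree()]).
#' @return List with `exact` (per-branch signature multisets identical),
#'   `n_true`, `n_matched` (true events matched on branch + type) and
#'   `type_recovery` (`n_matched / n_true`, 1 for an empty log).
#' @export
compare_event_logs <- function(log, placed) {
  true_sig <- log_signatures(log)
  inf_sig <- placed_signatures(placed)
  branches <- union(names(true_sig), names(inf_sig))
  exact <- all(vapply(branches, function(b)
    identical(sort(true_sig[[b]] %||% character(0)),
              sort(inf_sig[[b]] %||% character(0))), logical(1)))
  n_true <- nrow(log); matched <- 0L
  if (n_true) {
    inf_types <- placed[, c("branch", "type")]
    used <- rep(FALSE, nrow(inf_types))
    for (i in seq_len(n_true)) {
      j <- which(!used & inf_types$branch == log$branch[i] &
                   inf_types$type == log$type[i])
      if (length(j)) { used[j[1]] <- TRUE; matched <- matched + 1L }
    }
  }
  list(exact = exact, n_true = n_true, n_matched = matched,
       type_recovery = if (n_true) matched / n_true else 1)
}
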