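two_tip_scenario <- function(events = list(), wgd = character(0), ...) {
  scenario_spec("((tipA,tipB)ingroup,out)root;", events = events,
                wgd_branches = wgd, ...)
}

test_that("a WGD branch exactly doubles the karyotype", {
  anc <- build_teleost_ancestor(24L, genes_per_segment = 25L)
  sc <- two_tip_scenario(wgd = "tipA")
  sim <- simulate_karyotypes(anc, sc)
  expect_equal(length(unique(sim$tables$tipA$chromosome)), 48L)
  # each ancestral chromosome represented exactly twice
  tab <- table(sim$tables$tipA$true_color)
  expect_true(all(tab == 2L * ancestor_chromosome_sizes(anc)[names(tab)]))
  expect_equal(sim$tip_ploidy[["tipA"]], 2L)
  expect_equal(sim$tip_ploidy[["tipB"]], 1L)
})

test_that("an empty event history reproduces the ancestor at the tips", {
  anc <- build_teleost_ancestor(13L, genes_per_segment = 30L)
  sim <- simulate_karyotypes(anc, two_tip_scenario())
  tab <- sim$tables$tipB
  expect_equal(unique(tab$chromosome), names(anc$chromosomes))
  expect_equal(unname(table(tab$chromosome)[names(anc$chromosomes)]),
               unname(ancestor_chromosome_sizes(anc)), ignore_attr = TRUE)
  expect_true(all(tab$true_color == tab$chromosome))
})

test_that("fixed seeds make simulations byte-identical", {
  fs <- cypriniformes_scenario(genes_per_segment = 60L)
  s1 <- simulate_karyotypes(fs$ancestor, fs$scenario)
  s2 <- simulate_karyotypes(fs$ancestor, fs$scenario)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$log, s2$log)
})

test_that("gene loss lands inside the central 99% binomial interval", {
  anc <- build_teleost_ancestor(24L, genes_per_segment = 400L)
  n <- sum(ancestor_chromosome_sizes(anc))
  sc <- two_tip_scenario(loss_rate = 0.1, seed = 7L)
  sim <- simulate_karyotypes(anc, sc)
  kept <- nrow(sim$tables$tipA)
  # independent binomial quantiles for retention probability 0.9
  expect_gte(kept, qbinom(0.005, n, 0.9))
  expect_lte(kept, qbinom(0.995, n, 0.9))
})

test_that("structural closure: chromosome counts follow the event algebra", {
  for (seed in c(3L, 11L, 42L)) {
    rs <- random_scenario(seed, n_tips = 4L)
    sim <- simulate_karyotypes(rs$ancestor, rs$scenario)
    tree <- rs$scenario$tree
    n0 <- length(rs$ancestor$chromosomes)
    for (tip in tree$tip.label) {
      path <- karyopaint:::path_branches(tree, tip)
      expected <- n0
      for (b in path) {
        if (b %in% rs$scenario$wgd_branches) expected <- expected * 2L
        evs <- sim$log[sim$log$branch == b, , drop = FALSE]
        if (nrow(evs)) for (i in seq_len(nrow(evs))) {
          delta <- switch(evs$type[i], fusion = -1L, fission = +1L,
                          translocation = 0L, complex = +1L)
          expected <- expected + delta * evs$n_copies[i]
        }
      }
      expect_equal(unname(sim$node_chrom_counts[tip]), expected,
                   label = paste("tip", tip, "seed", seed))
    }
  }
})

test_that("conservation: tip gene counts equal ancestor genes times 2^WGDs", {
  fs <- cypriniformes_scenario(genes_per_segment = 40L)
  sim <- simulate_karyotypes(fs$ancestor, fs$scenario)
  n0 <- sum(ancestor_chromosome_sizes(fs$ancestor))
  for (tip in names(sim$tables))
    expect_equal(nrow(sim$tables[[tip]]), n0 * sim$tip_ploidy[[tip]],
                 label = tip)
})

test_that("events referencing missing chromosomes fail with branch and index", {
  anc <- build_teleost_ancestor(13L, genes_per_segment = 30L)
  sc <- two_tip_scenario(events = list(tipA = list(ev_fusion("T01", "T99"))))
  expect_error(simulate_karyotypes(anc, sc), "tipA.*event 1")
})

test_that("the packaged scenario matches its published description", {
  fs <- cypriniformes_scenario()
  ev <- fs$scenario$events
  types <- vapply(ev$cypriniformes, function(e) e$type, character(1))
  expect_length(ev$cypriniformes, 9L)
  expect_equal(sum(types == "fusion"), 2L)
  expect_equal(sum(types == "fission"), 1L)
  expect_equal(sum(types == "translocation"), 4L)
  expect_equal(sum(types == "complex"), 2L)
  expect_null(ev$zebrafish)        # zebrafish karyotype stays ancestral
  expect_null(ev$rare_minnow)
  expect_length(ev$grass_carp, 1L)
  expect_setequal(fs$scenario$wgd_branches, c("cyprinus", "sinocyclocheilus"))
  # stem events turn the 24-chromosome teleost ancestor into 25 chromosomes
  sim <- simulate_karyotypes(fs$ancestor, fs$scenario)
  expect_equal(unname(sim$node_chrom_counts["cypriniformes"]), 25L)
  expect_equal(unname(sim$node_chrom_counts["medaka"]), 24L)
})

test_that("replaying the log at zero noise is reflected in the tip tables", {
  # true colors at a tip partition exactly into the ancestor's gene content
  rs <- random_scenario(5L)
  sim <- simulate_karyotypes(rs$ancestor, rs$scenario)
  sizes <- ancestor_chromosome_sizes(rs$ancestor)
  for (tip in names(sim$tables)) {
    tab <- table(sim$tables[[tip]]$true_color)
    expect_equal(unname(tab[names(sizes)]),
                 unname(sizes * sim$tip_ploidy[[tip]]), ignore_attr = TRUE,
                 label = tip)
  }
})
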