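units_matrix <- function(...) {
  rows <- list(...)
  M <- do.call(rbind, rows)
  rownames(M) <- paste0("u", seq_len(nrow(M)))
  M
}

test_that("a 50/50 split of one color at ploidy 1 is one fission", {
  M <- matrix(c(200, 200), ncol = 1, dimnames = list(c("c1", "c2"), "f"))
  ev <- classify_events(M)
  expect_equal(ev$type, "fission")
  expect_equal(ev$colors, "f")
})

test_that("two co-major colors on one chromosome are one fusion", {
  M <- matrix(c(300, 280, 0, 0), nrow = 2,
              dimnames = list(c("c1", "c2"), c("g", "h")))
  M["c1", ] <- c(300, 280); M["c2", ] <- c(0, 0)
  ev <- classify_events(M[1, , drop = FALSE])
  expect_equal(ev$type, "fusion")
  expect_equal(ev$colors, "g,h")
})

test_that("a minority sliver away from home is a translocation", {
  M <- matrix(c(400, 0, 30, 370), nrow = 2,
              dimnames = list(c("c1", "c2"), c("a", "m")))
  ev <- classify_events(M)
  expect_equal(ev$type, "translocation")
  expect_equal(ev$donor, "m")
  expect_equal(ev$acceptor, "a")
  expect_equal(ev$colors, "a,m")
})

test_that("three major colors, or fusion+fission on one color, is complex", {
  M3 <- matrix(c(200, 180, 190), nrow = 1,
               dimnames = list("c1", c("x", "y", "z")))
  ev <- classify_events(M3)
  expect_equal(ev$type, "complex")
  expect_equal(ev$colors, "x,y,z")
  # fission of x whose distal part fused with y
  M <- units_matrix(c(240, 0), c(160, 160), c(0, 240))
  colnames(M) <- c("x", "y")
  ev <- classify_events(M)
  expect_equal(ev$type, "complex")
  expect_equal(ev$colors, "x,y")
  expect_equal(nrow(ev), 1L)   # primitive calls absorbed into one record
})

test_that("unfiltered compositions warn and are auto-filtered", {
  M <- matrix(c(400, 5), nrow = 1, dimnames = list("c1", c("a", "b")))
  expect_warning(ev <- classify_events(M), "auto-filter")
  expect_equal(nrow(ev), 0L)
  expect_error(classify_events(matrix(30, 1, 1, dimnames = list("c1", "zz")),
                               ancestor = build_teleost_ancestor(13L)),
               "unknown color")
})

test_that("classification is invariant to chromosome relabeling and rescaling", {
  rs <- random_scenario(9L, n_tips = 3L)
  sim <- simulate_karyotypes(rs$ancestor, rs$scenario)
  tab <- sim$tables[[1]]
  pk <- segment_blocks(filter_minor_colors(painted_karyotype(tab)), 1L)
  base <- classify_events(collapse_wgd(pk))
  # relabel chromosomes and rescale coordinates preserving order
  tab2 <- tab
  tab2$chromosome <- paste0("scf_", match(tab$chromosome,
                                          unique(tab$chromosome)))
  tab2$start <- tab2$start * 3L + 7L
  tab2$end <- tab2$start + 10L
  pk2 <- segment_blocks(filter_minor_colors(painted_karyotype(tab2)), 1L)
  ev2 <- classify_events(collapse_wgd(pk2))
  expect_equal(event_sigs(ev2), event_sigs(base))
})

test_that("classification matches the brute-force oracle on sampled small karyotypes", {
  set.seed(41)
  vals <- c(0, 25, 300)
  for (i in 1:400) {
    M <- matrix(sample(vals, 9, replace = TRUE), nrow = 3,
                dimnames = list(paste0("c", 1:3), c("p", "q", "r")))
    got <- event_sigs(suppressWarnings(classify_events(M)))
    want <- oracle_classify(M)
    expect_equal(got, want, label = paste("case", i))
  }
})

test_that("Dollo placement assigns clade-universal signatures to the stem", {
  tree <- read_tree("(((A,B)ab,C)abc,D)root;")
  ev <- function(colors) data.frame(
    type = "fusion", colors = colors, chromosomes = "x",
    donor = NA_character_, acceptor = NA_character_,
    signature = paste0("fusion:", colors), stringsAsFactors = FALSE)
  per <- list(A = rbind(ev("p,q"), ev("r,s")),
              B = rbind(ev("p,q"), ev("t,u")),
              C = ev("p,q"),
              D = ev("v,w"))
  placed <- place_on_tree(per, tree)
  expect_equal(placed$branch[placed$signature == "fusion:p,q"], "abc")
  expect_equal(placed$branch[placed$signature == "fusion:r,s"], "A")
  expect_equal(placed$branch[placed$signature == "fusion:v,w"], "D")
  # a non-clade pair gets two terminal assignments
  expect_setequal(placed$branch[placed$signature == "fusion:t,u"], "B")
  per2 <- list(A = ev("t,u"), C = ev("t,u"))
  placed2 <- place_on_tree(per2, tree)
  expect_setequal(placed2$branch, c("A", "C"))
  expect_equal(nrow(placed2), 2L)
  expect_error(place_on_tree(list(Z = ev("a,b")), tree), "absent from tree")
})

test_that("placement partitions every distinct signature", {
  for (seed in c(2L, 13L)) {
    rs <- random_scenario(seed, n_tips = 5L)
    res <- run_scenario_pipeline(rs$ancestor, rs$scenario,
                                 reconstruct = FALSE)
    n_sigs <- length(unique(unlist(lapply(res$events, function(e)
      e$signature))))
    expect_gte(nrow(res$placed), n_sigs)
    # each signature appears on >= 1 branch and its carriers are covered
    expect_equal(sort(unique(res$placed$signature)),
                 sort(unique(unlist(lapply(res$events, `[[`, "signature")))))
  }
})

test_that("event summaries have stable shape and zero-filled branches", {
  tree <- read_tree("((A,B)ab,C)root;")
  empty <- summarize_events(
    data.frame(branch = character(0), type = character(0)), tree)
  expect_equal(names(empty),
               c("branch", "fusion", "fission", "translocation", "complex",
                 "total"))
  expect_true(all(empty$total == 0L))
  expect_setequal(empty$branch, c("A", "B", "C", "ab"))
})
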