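test_that("best-hit resolution keeps the dominant hit under the E-value cutoff", {
  hits <- data.frame(
    qseqid = c("q1", "q1", "q2", "q3", "q3"),
    sseqid = c("s1", "s2", "s9", "sB", "sA"),
    evalue = c(1e-30, 1e-12, 1e-5, 1e-20, 1e-20),
    bitscore = c(200, 90, 80, 150, 150),
    stringsAsFactors = FALSE)
  map <- resolve_best_hits(hits, e_max = 1e-10)
  expect_equal(unname(map["q1"]), "s1")       # dominant bit score
  expect_false("q2" %in% names(map))          # sole hit above threshold
  expect_equal(unname(map["q3"]), "sA")       # lexicographic tie-break
})

test_that("malformed BLAST rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(paste(c("q1", "s1", "97.1", "200", "5", "0", "1", "200", "1",
                    "200", "1e-50", "300"), collapse = "\t"),
            paste(c("q2", "s2", "95.0", "bad", "5", "0", "1", "200", "1",
                    "200", "1e-40", "250"), collapse = "\t"))
  writeLines(rows, path)
  expect_error(read_blast_tab(path), "line 2")
  writeLines(rows[1], path)
  tab <- read_blast_tab(path)
  expect_equal(tab$qseqid, "q1")
  expect_equal(tab$bitscore, 300)
})

test_that("color assignment is a direct lookup preserving order and gaps", {
  genes <- data.frame(chromosome = "chr1", start = (0:3) * 100,
                      end = (0:3) * 100 + 50,
                      gene_id = c("g1", "g2", "g3", "g4"),
                      stringsAsFactors = FALSE)
  hit_map <- c(g1 = "p1", g3 = "p2")
  out <- assign_colors(genes, hit_map, c(p1 = "d", p2 = "a"))
  expect_equal(out$color, c("d", NA, "a", NA))
  expect_equal(out$gene_id, genes$gene_id)
  expect_error(assign_colors(genes, hit_map, c(p1 = "d")), "p2")
})

test_that("colored-gene counts equal an independent tally of the hit map", {
  set.seed(31)
  n <- 1000L
  genes <- data.frame(chromosome = "chr1", start = (seq_len(n) - 1L) * 10L,
                      end = (seq_len(n) - 1L) * 10L + 5L,
                      gene_id = sprintf("g%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  with_hits <- sample(genes$gene_id, 900L)
  hit_map <- setNames(sprintf("p%04d", seq_along(with_hits)), with_hits)
  anc_map <- setNames(rep(letters[1:10], length.out = length(hit_map)),
                      unname(hit_map))
  out <- assign_colors(genes, hit_map, anc_map)
  expect_equal(sum(!is.na(out$color)), length(hit_map))
})

test_that("the minor-color filter is strict 'fewer than' per chromosome", {
  pk <- toy_karyotype(chr1 = c(rep("a", 150), rep("b", 19)),
                      chr2 = rep("c", 20),
                      chr3 = rep(NA_character_, 5))
  out <- filter_minor_colors(pk, 20L)
  g <- out$genes
  expect_equal(sum(g$color == "a", na.rm = TRUE), 150L)
  expect_equal(sum(g$color == "b", na.rm = TRUE), 0L)     # 19 < 20 removed
  expect_equal(sum(g$color == "c", na.rm = TRUE), 20L)    # kept at exactly 20
  expect_true(all(is.na(g$color[g$chromosome == "chr3"])))
  expect_equal(g$gene_id, pk$genes$gene_id)               # order unchanged
})

test_that("filter thresholds nest and the filter is idempotent", {
  set.seed(17)
  for (rep in 1:5) {
    counts <- sample(1:40, 6, replace = TRUE)
    pk <- toy_karyotype(chr1 = rep(letters[1:6], counts),
                        chr2 = rep(letters[4:9], rev(counts)))
    kept <- function(p) {
      g <- p$genes[!is.na(p$genes$color), ]
      sort(unique(paste(g$chromosome, g$color)))
    }
    prev <- kept(pk)
    for (th in c(5L, 10L, 20L, 30L)) {
      cur <- kept(filter_minor_colors(pk, th))
      expect_true(all(cur %in% prev), label = paste("nesting at", th))
      prev <- cur
    }
    f1 <- filter_minor_colors(pk, 12L)
    expect_identical(filter_minor_colors(f1, 12L)$genes, f1$genes)
  }
})

test_that("segmentation produces maximal runs with transparent gaps", {
  pk <- segment_blocks(toy_karyotype(
    chr1 = c("a", "a", "a", "b", "b"),
    chr2 = c("a", NA, "a", "b", NA, "b", "a")), 1L)
  b1 <- pk$blocks[pk$blocks$chromosome == "chr1", ]
  expect_equal(b1$color, c("a", "b"))
  expect_equal(b1$gene_count, c(3L, 2L))
  b2 <- pk$blocks[pk$blocks$chromosome == "chr2", ]
  expect_equal(b2$color, c("a", "b", "a"))     # NA never breaks a block
  expect_equal(b2$gene_count, c(2L, 2L, 1L))
})

test_that("majority smoothing heals a single discordant gene", {
  pk <- segment_blocks(toy_karyotype(chr1 = c("a", "a", "b", "a", "a")), 3L)
  expect_equal(pk$blocks$color, "a")
  expect_equal(pk$blocks$gene_count, 5L)
  expect_error(segment_blocks(toy_karyotype(chr1 = c("a", "b")), 2L), "odd")
})

test_that("a single-color chromosome yields one block spanning it", {
  pk <- segment_blocks(toy_karyotype(chr1 = rep("m", 12)), 1L)
  expect_equal(nrow(pk$blocks), 1L)
  expect_equal(pk$blocks$gene_count, 12L)
  expect_equal(pk$blocks$start, pk$genes$start[1])
  expect_equal(pk$blocks$end, pk$genes$end[12])
})

test_that("segmentation conserves colored genes and is idempotent at w=1", {
  set.seed(23)
  for (rep in 1:20) {
    cols <- sample(c("a", "b", "c", NA), 12, replace = TRUE)
    pk <- toy_karyotype(chr1 = cols)
    seg <- segment_blocks(pk, 1L)
    expect_equal(sum(seg$blocks$gene_count), sum(!is.na(cols)))
    # matches the brute-force run-length oracle
    expect_equal(seg$blocks[, c("color", "gene_count")], oracle_runs(cols),
                 ignore_attr = TRUE)
    seg2 <- segment_blocks(seg, 1L)
    expect_identical(seg2$blocks, seg$blocks)
  }
})

test_that("composition matrices count colored genes per chromosome", {
  pk <- toy_karyotype(chr1 = c("a", "a", "b", NA), chr2 = c("b", "b"))
  M <- composition_matrix(pk)
  expect_equal(M["chr1", "a"], 2L, ignore_attr = TRUE)
  expect_equal(M["chr1", "b"], 1L, ignore_attr = TRUE)
  expect_equal(M["chr2", "b"], 2L, ignore_attr = TRUE)
  expect_equal(sum(M), 5)
})
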