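delta_hist <- function(peak_depth = 20L, n_kmers = 1.53e9, pad = 40L) {
  data.frame(depth = seq_len(pad),
             n_kmers = ifelse(seq_len(pad) == peak_depth, n_kmers, 0))
}

test_that("genome size is total k-mers over the modal coverage depth", {
  h <- delta_hist(20L, 1.53e9)
  est <- estimate_genome_size(h)
  expect_equal(est$peak_depth, 20)
  # 3.06e10 k-mers at depth 20 -> 1.53 Gb
  expect_equal(est$total_kmers, 3.06e10)
  expect_equal(est$size_bp, 1.53e9)
})

test_that("the mode search skips the error peak but the total includes it", {
  h <- data.frame(depth = 1:50,
                  n_kmers = c(5e7, 1e6, rep(0, 20),
                              0, 2e6, 8e8, 2e6, rep(0, 24)))
  est <- estimate_genome_size(h)
  expect_equal(est$peak_depth, 25)  # mode after the first local minimum
  expect_equal(est$total_kmers, sum(h$depth * h$n_kmers))
  excl <- estimate_genome_size(h, exclude_error = TRUE)
  expect_lt(excl$size_bp, est$size_bp)
})

test_that("degenerate histograms are rejected", {
  expect_error(estimate_genome_size(data.frame(depth = numeric(0),
                                               n_kmers = numeric(0))),
               "empty")
  mono <- data.frame(depth = 1:10, n_kmers = rev(1:10) * 1e5)
  expect_error(estimate_genome_size(mono), "no coverage peak")
  expect_error(estimate_genome_size(data.frame(depth = c(2, 2),
                                               n_kmers = c(1, 1))),
               "strictly increasing")
})

test_that("delta-spike histograms are estimated to machine precision", {
  # a spike of N k-mers at depth d is a genome of N distinct k-mers
  for (d in c(7L, 20L, 33L)) {
    size <- 1e9 + d * 1234
    h <- delta_hist(d, size)
    est <- estimate_genome_size(h)
    expect_equal(est$peak_depth, d)
    expect_lt(abs(est$size_bp - size) / size, 1e-12)
  }
})

test_that("Poisson-shaped histograms recover the underlying size within 2%", {
  G <- 1e6; lambda <- 40.5   # non-integer rate: unique modal depth at 40
  depths <- 1:120
  n <- round(G * dpois(depths, lambda))
  n[1] <- n[1] + 2000   # small error spike
  h <- data.frame(depth = depths, n_kmers = n)
  est <- estimate_genome_size(h)
  expect_equal(est$peak_depth, floor(lambda))
  expect_lt(abs(est$size_bp - G) / G, 0.02)
  # the weighted-mean alternative is tighter still
  est2 <- estimate_genome_size(h, mean_mode = TRUE, exclude_error = TRUE)
  expect_lt(abs(est2$size_bp - G) / G, 0.01)
})

telo <- function(n) strrep("TTAGGG", n)
rc_telo <- function(n) strrep("CCCTAA", n)
filler <- function(n) strrep("ACGTGCAT", ceiling(n / 8)) |> substr(1, n)

test_that("terminal repeat arrays are detected on the correct ends", {
  seqs <- c(both = paste0(telo(200), filler(20000), rc_telo(200)),
            left = paste0(telo(80), filler(20000)),
            weak = paste0(telo(10), filler(20000)),
            none = filler(20000))
  hits <- find_telomeres(seqs, min_copies = 50L)
  expect_equal(nrow(hits), 3L)
  expect_setequal(hits$end[hits$seqid == "both"], c("left", "right"))
  expect_equal(hits$copies[hits$seqid == "both" & hits$end == "left"], 200L)
  expect_equal(hits$end[hits$seqid == "left"], "left")
  expect_false("weak" %in% hits$seqid)   # 10 copies under min_copies=50
})

test_that("reverse-complementing every sequence swaps ends, keeps totals", {
  seqs <- c(s1 = paste0(telo(120), filler(15000)),
            s2 = paste0(filler(15000), rc_telo(90)))
  rcseq <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  h1 <- find_telomeres(seqs, min_copies = 50L)
  h2 <- find_telomeres(rcseq, min_copies = 50L)
  expect_equal(nrow(h1), nrow(h2))
  flip <- c(left = "right", right = "left")
  for (i in seq_len(nrow(h1))) {
    j <- which(h2$seqid == h1$seqid[i])
    expect_equal(h2$end[j], unname(flip[h1$end[i]]))
  }
})

test_that("FASTA input works and non-IUPAC characters only warn", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", paste0(telo(60), filler(2000)),
               ">chr2", filler(2000)), fa)
  hits <- find_telomeres(fa, window_bp = 1000L, min_copies = 50L)
  expect_equal(hits$seqid, "chr1")
  writeLines(c(">odd", paste0(telo(60), "JJJJ", filler(2000))), fa)
  expect_warning(find_telomeres(fa, window_bp = 1000L, min_copies = 50L),
                 "non-IUPAC")
})

test_that("telomere counting reports totals, T2T sequences and missing ends", {
  mk <- function(seqid, end) data.frame(seqid = seqid, end = end,
                                        copies = 100L, window_bp = 10000L,
                                        stringsAsFactors = FALSE)
  ids <- sprintf("chr%02d", 1:50)
  full <- do.call(rbind, lapply(ids, function(s)
    rbind(mk(s, "left"), mk(s, "right"))))
  res <- count_telomeres(full, 50L, seqids = ids)
  expect_equal(res$total, 100L)
  expect_equal(res$t2t, 50L)
  expect_equal(nrow(res$missing), 0L)
  one_short <- full[-100, ]
  res99 <- count_telomeres(one_short, 50L, seqids = ids)
  expect_equal(res99$total, 99L)
  expect_equal(res99$t2t, 49L)
  expect_equal(res99$missing$seqid, "chr50")
  empty <- count_telomeres(full[0, ], 50L)
  expect_equal(empty$total, 0L)
  # invariants: order invariance and the 2n bound
  shuf <- full[sample(nrow(full)), ]
  expect_equal(count_telomeres(shuf, 50L)$total, 100L)
  expect_error(count_telomeres(full, 40L), "at most one hit per end")
})

test_that("histogram files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".histo")
  writeLines(c("1 50000", "2 1000", "19 5000", "20 90000", "21 4000"), path)
  h <- read_kmer_histogram(path, k = 17L)
  expect_equal(attr(h, "k"), 17L)
  expect_equal(h$depth, c(1L, 2L, 19L, 20L, 21L))
  est <- estimate_genome_size(h)
  expect_equal(est$peak_depth, 20)
})
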