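test_that("in silico digestion labels both strands and handles edge cases", {
  expect_equal(length(in_silico_digest("")), 0L)
  expect_equal(in_silico_digest("")$length_bp, 0)

  m <- in_silico_digest("GCTCTTC")
  expect_equal(m$positions, 0)
  expect_equal(m$strands, "+")

  # one forward and one reverse site
  m2 <- in_silico_digest("GCTCTTCAAAAGAAGAGC")
  expect_equal(m2$positions, c(0, 17))
  expect_equal(m2$strands, c("+", "-"))

  expect_error(in_silico_digest("ACGTX"), "only")
})

test_that("digestion matches an independent regex scan on random sequences", {
  set.seed(42)
  for (rep in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 100000, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    m <- in_silico_digest(seq)
    expect_equal(m$positions, oracle_digest_positions(seq))
  }
})

test_that("digestion is strand-symmetric", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
               collapse = "")
  revcomp <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  m <- in_silico_digest(seq)
  mr <- in_silico_digest(revcomp)
  expect_equal(mr$positions, rev(nchar(seq) - 1 - m$positions))
})

test_that("gap intervals are maximal N runs partitioning the N bases", {
  expect_equal(nrow(find_gap_intervals("ACGTACGT")), 0L)
  g <- find_gap_intervals("ACGTNNNNAC")
  expect_equal(unlist(g), c(start = 4, end = 8))

  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 5000, replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
  g <- find_gap_intervals(seq)
  o <- oracle_n_runs(seq)
  expect_equal(as.matrix(g), o, ignore_attr = TRUE)
  # total gap length equals the N count
  expect_equal(sum(g$end - g$start),
               lengths(regmatches(seq, gregexpr("N", seq))))
})

test_that("subtelomere windows are re-coordinated toward the telomere", {
  chrom <- label_map("chr", 2e6, c(100000, 1600000, 1900000))
  w <- extract_subtelomere_window(chrom, arm = "testq", window_bp = 500000)
  expect_equal(w$map$positions, c(100000, 400000))
  expect_equal(w$tel_end_bp, 500000)

  # p arm: mirrored; applying the mirror twice restores the input
  wp <- extract_subtelomere_window(chrom, arm = "testp", window_bp = 500000)
  expect_equal(wp$map$positions, 500000 - 1 - 100000)
  expect_equal(reverse_map(reverse_map(wp$map))$positions, wp$map$positions)

  # inter-label distances preserved
  q <- label_map("chr", 2e6, c(1550000, 1600000, 1725000))
  wq <- extract_subtelomere_window(q, arm = "xq", window_bp = 500000)
  expect_equal(diff(wq$map$positions), diff(q$positions))

  # terminal 110-kb N run pulls the sequenced end back
  gaps <- gap_intervals(2e6 - 110000, 2e6)
  wg <- extract_subtelomere_window(chrom, gaps, arm = "xq",
                                   window_bp = 500000)
  expect_equal(wg$tel_end_bp, 500000 - 110000)
  expect_equal(wg$arm_end_bp, 500000)

  expect_warning(extract_subtelomere_window(label_map("s", 3e5, c(1e5)),
                                            arm = "sq"),
                 "shorter")
})

test_that("CMAP dialect round-trips and rejects malformed input", {
  maps <- list(label_map("a", 50000, c(100, 20000, 49000)),
               label_map("b", 10000, numeric(0)))
  path <- tempfile(fileext = ".cmap")
  write_cmap(maps, path)
  back <- read_cmap(path)
  expect_equal(back[["a"]]$positions, maps[[1]]$positions)
  expect_equal(back[["a"]]$length_bp, maps[[1]]$length_bp)
  expect_equal(length(back[["b"]]), 0L)

  write_cmap(list(), path)
  expect_equal(read_cmap(path), list())

  # unsorted positions violate the invariant
  writeLines(c("#h header",
               "x\t1000\t2\t1\t1\t500",
               "x\t1000\t2\t2\t1\t300",
               "x\t1000\t2\t3\t0\t1000"), path)
  expect_error(read_cmap(path), "unsorted")

  # extra columns are tolerated
  writeLines(c("x\t1000\t1\t1\t1\t500\textra",
               "x\t1000\t1\t2\t0\t1000\textra"), path)
  expect_equal(read_cmap(path)[["x"]]$positions, 500)
})

test_that("BED gap files round-trip", {
  g <- list(chrA = gap_intervals(c(0, 500), c(100, 900)),
            chrB = gap_intervals(10, 20))
  path <- tempfile(fileext = ".bed")
  write_gaps_bed(g, path)
  back <- read_gaps_bed(path)
  expect_equal(back$chrA, g$chrA)
  expect_equal(back$chrB, g$chrB)
})

test_that("FASTA digestion builds reference arms end to end", {
  fa <- tempfile(fileext = ".fa")
  set.seed(3)
  body <- paste(sample(c("A", "C", "G", "T"), 600000, replace = TRUE),
                collapse = "")
  seq <- paste0(substr(body, 1, 599000),
                paste(rep("N", 1000), collapse = ""))
  writeLines(c(">synq", seq), fa)
  arms <- digest_fasta(fa, window_bp = 500000)
  expect_equal(arms$synq$arm, "synq")
  expect_equal(arms$synq$tel_end_bp, 500000 - 1000)
  expect_gt(length(arms$synq$map$positions), 0)
})
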