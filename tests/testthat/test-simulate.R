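test_that("haplotype composition concatenates anchor and block patterns", {
  lib <- default_block_library()
  bare <- compose_haplotype(haplotype_spec("h0", "5q"), lib)
  expect_true(all(bare$positions < 300000))
  expect_equal(nrow(attr(bare, "truth")), 0L)

  h <- compose_haplotype(haplotype_spec("h1", "5q", c("B1", "B3")), lib)
  truth <- attr(h, "truth")
  expect_equal(truth$block, c("B1", "B3"))
  # spacings inside each block interval equal the library vectors
  for (k in seq_len(nrow(truth))) {
    inb <- h$positions[h$positions >= truth$start[k] &
                         h$positions <= truth$end[k]]
    expect_equal(diff(inb), lib[[truth$block[k]]]$label_spacings)
  }
  # reversed block: mirrored spacing vector
  hr <- compose_haplotype(haplotype_spec("h2", "5q", c("B3-")), lib)
  tr <- attr(hr, "truth")
  inb <- hr$positions[hr$positions >= tr$start & hr$positions <= tr$end]
  expect_equal(diff(inb), rev(lib$B3$label_spacings))

  expect_error(compose_haplotype(haplotype_spec("h3", "5q", "nope"), lib),
               "unknown block")
})

test_that("reference arms pad the terminal gap with unlabelled N", {
  spec <- haplotype_spec("ref", "18q", c("B6"), terminal_gap_bp = 110000)
  arm <- build_reference_arm(spec)
  expect_equal(arm$arm_end_bp - arm$tel_end_bp, 110000)
  expect_equal(nrow(arm$gaps), 1L)
  expect_true(all(arm$map$positions < arm$tel_end_bp))
})

test_that("population sampling matches its frequency design", {
  pops <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  one <- matrix(1, 5, 1, dimnames = list(pops, "h"))
  pop <- population_spec(freqs = list(aq = one))
  d <- sample_population(pop, seed = 5)
  expect_equal(length(unique(d$genome)), 154L)
  expect_true(all(d$hap1 == "h" & d$hap2 == "h"))
  expect_equal(as.integer(table(unique(d[, 1:2])$superpop)[pops]),
               c(42, 30, 30, 24, 28))

  # 50/50 design: carrier fraction within 3 binomial SD
  half <- matrix(0.5, 5, 2, dimnames = list(pops, c("a", "b")))
  d2 <- sample_population(population_spec(freqs = list(aq = half)), seed = 6)
  frac <- mean(c(d2$hap1, d2$hap2) == "a")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (2 * 154)))

  # reproducible under seed
  expect_identical(d2, sample_population(population_spec(freqs = list(aq = half)),
                                         seed = 6))

  bad <- matrix(c(0.6, 0.6, rep(0.5, 8)), 5, 2,
                dimnames = list(pops, c("a", "b")))
  expect_error(population_spec(freqs = list(aq = bad)), "sum to 1")
})

test_that("error-free molecules are exact slices of the truth", {
  truth <- rand_map(60, seed = 9)
  p0 <- pipeline_params(fp_rate = 0, fn_rate = 0, sizing_cv = 0,
                        jitter_bp = 0)
  mols <- simulate_molecules(truth, p0, seed = 2, coverage = 10,
                             orient_random = FALSE)
  for (m in mols) {
    want <- truth$positions[truth$positions >= m$start &
                              truth$positions < m$start + m$map$length_bp]
    expect_equal(m$map$positions + round(m$start), round(want),
                 tolerance = 1e-8)
  }
})

test_that("label error rates in simulated molecules match the design", {
  truth <- rand_map(80, seed = 10, min_gap = 4000, max_gap = 10000)
  # false negatives isolated from position noise: surviving labels sit
  # exactly on truth, so the drop rate is counted directly
  p_fn <- pipeline_params(fp_rate = 0, sizing_cv = 0, jitter_bp = 0)
  mols_fn <- simulate_molecules(truth, p_fn, seed = 3,
                                orient_random = FALSE)
  n_true_cov <- 0; n_seen <- 0
  for (m in mols_fn) {
    want <- truth$positions[truth$positions >= m$start &
                              truth$positions < m$start + m$map$length_bp] -
      round(m$start)
    n_true_cov <- n_true_cov + length(want)
    n_seen <- n_seen + sum(want %in% m$map$positions)
  }
  fn_obs <- 1 - n_seen / n_true_cov
  expect_lt(abs(fn_obs - p_fn$fn_rate),
            3 * sqrt(p_fn$fn_rate * (1 - p_fn$fn_rate) / n_true_cov))

  # expected observed label count at full defaults:
  # n_true (1 - fn) + lambda_fp * length
  p <- pipeline_params()
  mols <- simulate_molecules(truth, p, seed = 3, orient_random = FALSE)
  n_true_cov <- 0
  for (m in mols) {
    n_true_cov <- n_true_cov +
      sum(truth$positions >= m$start &
            truth$positions < m$start + m$map$length_bp)
  }
  tot_obs <- sum(vapply(mols, function(m) length(m$map$positions), 0))
  lambda <- p$fp_rate / (1 - p$fp_rate) * (1 - p$fn_rate) *
    length(truth$positions) / truth$length_bp
  tot_len <- sum(vapply(mols, function(m) m$map$length_bp, 0))
  expected <- n_true_cov * (1 - p$fn_rate) + lambda * tot_len
  expect_lt(abs(tot_obs - expected), 3 * sqrt(expected))

  # coverage target reached
  expect_gte(tot_len / truth$length_bp, p$min_coverage)
})

test_that("forced INP breakage prevents any molecule from spanning the site", {
  truth <- rand_map(80, seed = 12)
  p <- pipeline_params(p_break = 1)
  site <- truth$length_bp / 2
  mols <- simulate_molecules(truth, p, inp_sites = site, seed = 4,
                             coverage = 20, orient_random = FALSE)
  spans <- vapply(mols, function(m)
    m$start < site - 1 && m$start + m$map$length_bp > site + 1, TRUE)
  expect_false(any(spans))
  expect_true(any(vapply(mols, function(m) m$broken_at_inp, TRUE)))

  expect_error(simulate_molecules(label_map("s", 100000, 50000),
                                  pipeline_params()),
               "shorter")
})

test_that("BNX dialect round-trips molecules with their truth", {
  truth <- rand_map(40, seed = 13)
  mols <- simulate_molecules(truth, pipeline_params(), seed = 5,
                             coverage = 5, genome = "G1", arm = "3q",
                             hap = "h1")
  path <- tempfile(fileext = ".bnx")
  write_bnx(mols, path)
  back <- read_bnx(path)
  expect_equal(length(back), length(mols))
  k <- length(mols)
  expect_equal(back[[k]]$map$positions, mols[[k]]$map$positions)
  expect_equal(back[[k]]$genome, "G1")
  expect_equal(back[[k]]$telomere_label, mols[[k]]$telomere_label)
  expect_equal(back[[k]]$flipped, mols[[k]]$flipped)

  write_bnx(list(), path)
  expect_equal(read_bnx(path), list())

  writeLines(c("# header", "0\tm1\t200000", "not a label line"), path)
  expect_error(read_bnx(path), "line")
})
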