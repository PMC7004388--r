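test_that("chunk scores follow the sizing-error model", {
  p <- pipeline_params()
  # perfect interval: reward only
  expect_equal(chunk_score(8000, 8000, 0, 0, p), p$match_reward)
  # direct formula evaluation
  v <- p$sizing_cv^2 * 9000^2 + 2 * p$jitter_bp^2
  want <- p$match_reward - (7000 - 9000)^2 / (2 * v) -
    2 * p$fp_penalty - 1 * p$fn_penalty
  expect_equal(chunk_score(7000, 9000, 2, 1, p), want)
  # widening |dq - dr| strictly decreases the score
  ds <- vapply(seq(0, 5000, by = 500), function(d)
    chunk_score(8000 + d, 8000, 0, 0, p), 0)
  expect_true(all(diff(ds) < 0))
  # swapping roles swaps the penalties symmetrically
  expect_equal(chunk_score(7000, 7000, 2, 1, p),
               chunk_score(7000, 7000, 1, 2,
                           pipeline_params(fp_penalty = p$fn_penalty,
                                           fn_penalty = p$fp_penalty)))
})

test_that("fit alignment recovers exact slices in either orientation", {
  p <- pipeline_params()
  target <- rand_map(60, seed = 21)
  q <- slice_map(target, 100000, 280000, "q")
  a <- align_fit(q, target, p, min_aligned = 3, min_score = 0)
  expect_equal(a$orientation, "+")
  expect_equal(a$n_pairs, length(q$positions))
  expect_equal(target$positions[a$pairs[, "ti"]] - 100000,
               q$positions[a$pairs[, "qi"]])

  ar <- align_fit(reverse_map(q), target, p, min_aligned = 3, min_score = 0)
  expect_equal(ar$orientation, "-")
  expect_equal(ar$score, a$score)

  # translation of both maps leaves the score unchanged
  shift <- function(m, d) label_map(m$id, m$length_bp + d, m$positions + d)
  a2 <- align_fit(shift(q, 5000), shift(target, 5000), p,
                  min_aligned = 3, min_score = 0)
  expect_equal(a2$score, a$score)
})

test_that("overlap alignment finds dovetails and rejects unrelated maps", {
  p <- pipeline_params()
  truth <- rand_map(80, seed = 22)
  a_map <- slice_map(truth, 0, 350000, "a")
  b_map <- slice_map(truth, 150000, 500000, "b")
  ov <- align_overlap(a_map, b_map, p)
  expect_false(is.null(ov))
  expect_equal(ov$offset, -150000)

  u <- rand_map(40, seed = 23)
  v <- rand_map(40, seed = 24)
  expect_null(align_overlap(u, v, p))
})

test_that("dynamic programming equals exhaustive enumeration on small maps", {
  p <- pipeline_params(max_skip = 2)
  for (k in 1:120) {
    set.seed(3000 + k)
    q <- rand_map(sample(2:8, 1), seed = 2 * k + 1)
    t <- rand_map(sample(2:8, 1), seed = 2 * k + 2)
    for (mode in c("fit", "overlap")) {
      o <- oracle_align_score(q, t, p, mode)
      a <- if (mode == "fit")
        align_fit(q, t, p, min_aligned = 1, min_score = -Inf)
      else align_overlap(q, t, p, min_aligned = 1, min_score = -Inf)
      expect_equal(a$score, o, tolerance = 1e-6,
                   label = sprintf("case %d mode %s", k, mode))
    }
  }
})

test_that("self-alignment dominates alignments to unrelated maps", {
  p <- pipeline_params()
  for (k in 1:10) {
    m <- rand_map(20, seed = 100 + k)
    other <- rand_map(20, seed = 200 + k)
    self <- align_fit(m, m, p, min_aligned = 1, min_score = -Inf)
    cross <- align_fit(m, other, p, min_aligned = 1, min_score = -Inf)
    expect_gte(self$score, cross$score)
  }
})

test_that("alignment tables summarise accepted alignments", {
  p <- pipeline_params()
  t1 <- rand_map(50, seed = 31)
  q1 <- slice_map(t1, 50000, 250000, "q1")
  tab <- alignment_table(list(align_fit(q1, t1, p, min_aligned = 3,
                                        min_score = 0), NULL))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$query, "q1")
  expect_equal(tab$score_per_label, tab$score / tab$n_pairs)
})
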