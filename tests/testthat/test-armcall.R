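p_def <- pipeline_params()

## two synthetic arms sharing block content but with distinct 1-copy
## anchor patterns
mk_arms <- function() {
  lib <- default_block_library()
  s1 <- haplotype_spec("ref", "aq", c("B1", "B5"), terminal_gap_bp = 0)
  s2 <- haplotype_spec("ref", "bq", c("B1", "B5"), terminal_gap_bp = 0)
  list(aq = build_reference_arm(s1, lib), bq = build_reference_arm(s2, lib))
}

test_that("contigs anchor to the arm with the matching 1-copy pattern", {
  arms <- mk_arms()
  anc <- anchor_to_arm(arms$aq$map, arms, p_def)
  expect_equal(anc$arm, "aq")
  anc2 <- anchor_to_arm(arms$bq$map, arms, p_def)
  expect_equal(anc2$arm, "bq")

  # a mirrored contig anchors too, normalised to '+'
  anc3 <- anchor_to_arm(reverse_map(arms$aq$map), arms, p_def)
  expect_equal(anc3$arm, "aq")
  expect_true(anc3$flipped)
  expect_equal(anc3$alignment$orientation, "+")

  # a blocks-only contig has no 1-copy anchor: ambiguous
  lib <- default_block_library()
  blocks_only <- label_map("blk", 120000,
                           cumsum(c(2000, lib$B1$label_spacings, 6000,
                                    lib$B5$label_spacings)))
  expect_null(anchor_to_arm(blocks_only, arms, p_def))
})

test_that("extension measurement rounds at the reporting resolution", {
  arms <- mk_arms()
  arm <- arms$aq
  anc <- anchor_to_arm(arm$map, arms, p_def)
  ext <- measure_extension(anc, arm, p_def)
  expect_equal(ext$extension_called_bp, 0)
  expect_equal(ext$gap_correction_called_bp, 0)

  # a contig ending 5 kb past the end is still called 0
  longer <- label_map("l", arm$map$length_bp + 5000, arm$map$positions)
  anc2 <- anchor_to_arm(longer, arms, p_def)
  ext2 <- measure_extension(anc2, arm, p_def)
  expect_equal(ext2$extension_called_bp, 0)

  # 45 kb past the end is called as such
  ext_pos <- c(arm$map$positions, arm$map$length_bp + c(10000, 25000, 40000))
  longer2 <- label_map("l2", arm$map$length_bp + 45000, ext_pos)
  anc3 <- anchor_to_arm(longer2, arms, p_def)
  ext3 <- measure_extension(anc3, arm, p_def)
  expect_equal(ext3$extension_called_bp, 45000)
})

test_that("gap assessment distinguishes DELETE, EXTEND, SUPPORTED, INACCURATE", {
  lib <- default_block_library()
  spec <- haplotype_spec("ref", "gq", c("B6"), terminal_gap_bp = 110000)
  arm <- build_reference_arm(spec, lib)
  arms <- list(gq = arm)
  seqmap <- label_map("m", arm$tel_end_bp, arm$map$positions)

  # contig ending exactly at the gap start: DELETE with -110 kb correction
  anc <- anchor_to_arm(seqmap, arms, p_def)
  ext <- measure_extension(anc, arm, p_def)
  expect_equal(ext$gap_correction_called_bp, -110000)
  expect_equal(assess_gap(anc, arm, ext, p_def), "DELETE")

  # contig reaching past the annotated end: EXTEND
  far <- label_map("f", arm$arm_end_bp + 30000,
                   c(arm$map$positions, arm$arm_end_bp + c(5000, 20000)))
  anc2 <- anchor_to_arm(far, arms, p_def)
  ext2 <- measure_extension(anc2, arm, p_def)
  expect_equal(assess_gap(anc2, arm, ext2, p_def), "EXTEND")

  # contig ending inside the gap: SUPPORTED
  mid <- label_map("s", arm$tel_end_bp + 50000, arm$map$positions)
  anc3 <- anchor_to_arm(mid, arms, p_def)
  ext3 <- measure_extension(anc3, arm, p_def)
  expect_equal(assess_gap(anc3, arm, ext3, p_def), "SUPPORTED")

  # gapless arm, contig matching through its end: SUPPORTED at 0
  spec0 <- haplotype_spec("ref", "hq", c("B6"))
  arm0 <- build_reference_arm(spec0, lib)
  anc0 <- anchor_to_arm(arm0$map, list(hq = arm0), p_def)
  ext0 <- measure_extension(anc0, arm0, p_def)
  expect_equal(assess_gap(anc0, arm0, ext0, p_def), "SUPPORTED")

  # anchor aligns but the distal pattern conflicts: INACCURATE
  spec_alt <- haplotype_spec("alt", "gq", c("B3-"), terminal_gap_bp = 0)
  altmap <- compose_haplotype(spec_alt, lib)
  anc4 <- anchor_to_arm(altmap, arms, p_def)
  expect_false(is.null(anc4))
  ext4 <- measure_extension(anc4, arm, p_def)
  expect_equal(assess_gap(anc4, arm, ext4, p_def), "INACCURATE")
})

test_that("telomere confirmation needs concordant labelled molecule ends", {
  sc <- cached("sc18", scenario_gap_overestimate())
  asm_on <- cached("asm18", {
    mols <- simulate_molecules(sc$true_map, p_def, seed = 11)
    assemble_molecules(mols, p_def)
  })
  cons <- asm_on$contigs[[1]]
  anc <- anchor_to_arm(cons, list("18q" = sc$ref_arm), p_def)
  expect_true(confirm_telomere(cons, p_def, telomere_right = !anc$flipped))

  # labelling off: never confirmed
  asm_off <- cached("asm18_off", {
    mols <- simulate_molecules(sc$true_map, p_def, seed = 11,
                               telomere_labeling = FALSE)
    assemble_molecules(mols, p_def)
  })
  c_off <- asm_off$contigs[[1]]
  anc_off <- anchor_to_arm(c_off, list("18q" = sc$ref_arm), p_def)
  expect_false(confirm_telomere(c_off, p_def,
                                telomere_right = !anc_off$flipped))

  # a contig truncated 50 kb short of the true end: labelled ends overshoot
  tr <- cons
  telo_right <- !anc$flipped
  if (telo_right) {
    keep <- tr$map$positions <= tr$map$length_bp - 50000
    tr$map <- label_map(tr$map$id, tr$map$length_bp - 50000,
                        tr$map$positions[keep])
  } else {
    tr$members$start <- tr$members$start - 50000
  }
  expect_false(confirm_telomere(tr, p_def, telomere_right = telo_right))
})

test_that("INP scanning equals a brute-force opposing-strand pair scan", {
  expect_equal(nrow(scan_inp(label_map("x", 10000, c(100, 5000),
                                       strands = c("+", "+")), 1000)), 0L)
  one <- scan_inp(label_map("y", 20000, c(10000, 10500),
                            strands = c("+", "-")), 1000)
  expect_equal(one$position, 10250)
  expect_equal(one$distance, 500)

  set.seed(51)
  pos <- cumsum(round(runif(60, 200, 3000)))
  strands <- sample(c("+", "-"), 60, replace = TRUE)
  m <- label_map("z", max(pos) + 100, pos, strands = strands)
  got <- scan_inp(m, 1000)
  want <- oracle_inp(pos, strands, 1000)
  expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
  if (!is.null(want)) {
    expect_equal(got$position, want[, 1])
    expect_equal(got$distance, want[, 2])
  }
  expect_error(scan_inp(label_map("w", 1000, 10), 1000), "strand")
})

test_that("haplotype clustering separates terminal differences above resolution", {
  arms <- mk_arms()
  m <- arms$aq$map
  same5 <- label_map("s5", m$length_bp + 5000, m$positions)
  plus45 <- label_map("p45", m$length_bp + 45000,
                      c(m$positions, m$length_bp + c(15000, 30000)))
  calls <- data.frame(contig = c("a", "b", "c"),
                      extension_bp = c(0, 5000, 45000))
  cl <- cluster_haplotypes(calls, list(m, same5, plus45), p_def)
  expect_equal(cl[1], cl[2])   # 5-kb difference: indistinguishable
  expect_false(cl[3] == cl[1]) # 45-kb difference: separate haplotype
  # permutation invariance of the partition
  cl2 <- cluster_haplotypes(calls[c(3, 1, 2), ],
                            list(plus45, m, same5), p_def)
  expect_equal(cl2[2], cl2[3])
  expect_false(cl2[1] == cl2[2])
  # identical contigs collapse to the single major cluster
  expect_equal(cluster_haplotypes(calls[c(1, 1), ], list(m, m), p_def),
               c(1L, 1L))
})

test_that("variability classification applies the strict 10% rule", {
  expect_equal(classify_variability(c(100)), "LOW")
  expect_equal(classify_variability(c(125, 17)), "HIGH")
  expect_equal(classify_variability(c(90, 10)), "LOW")
  expect_equal(classify_variability(c(89, 10, 1)), "HIGH")
})

test_that("arm summaries aggregate counts and conserve the cohort", {
  empty <- summarize_arm(data.frame(), arm = "xq", n_failed = 3)
  expect_equal(empty$n_represented, 0L)
  expect_equal(empty$variability, "NA")

  calls <- data.frame(arm = "2q",
                      cluster = rep(1:3, c(110, 20, 3)),
                      extension_called_bp = rep(c(0, 45000, 0),
                                                c(110, 20, 3)),
                      gap_correction_called_bp = rep(c(0, 35000, 0),
                                                     c(110, 20, 3)))
  s <- summarize_arm(calls, n_failed = 21)
  expect_equal(s$n_represented, 133L)
  expect_equal(s$cluster_sizes, "110,20,3")
  expect_equal(s$variability, "HIGH")
  expect_equal(s$n_represented + s$n_failed, 154L)
})
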