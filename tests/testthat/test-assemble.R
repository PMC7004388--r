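p0 <- pipeline_params(fp_rate = 0, fn_rate = 0, sizing_cv = 0,
                      jitter_bp = 0)

test_that("overlap graph edges carry correct offsets and are pruned", {
  truth <- rand_map(100, seed = 41)
  # two molecules with a 100-kb overlap: one edge, correct offset
  two <- tile_molecules(slice_map(truth, 0, 500000, "t2"), n = 2,
                        mol_len = 300000)
  g2 <- build_overlap_graph(two, p0)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$offset, 200000)

  # three collinear molecules: transitive edge removed, chain remains
  three <- tile_molecules(slice_map(truth, 0, 560000, "t3"), n = 3,
                          mol_len = 300000)
  g3 <- build_overlap_graph(three, p0)
  expect_equal(nrow(g3$edges), 2L)
  expect_equal(sort(paste(g3$edges$from, g3$edges$to)), c("1 2", "2 3"))

  # unrelated random molecules: no edges at calibrated thresholds
  unrel <- lapply(1:6, function(k) {
    structure(list(map = rand_map(30, seed = 400 + k), genome = NA,
                   arm = NA, hap = NA, start = 0, telomere_label = FALSE,
                   broken_at_inp = FALSE, flipped = FALSE),
              class = "sim_molecule")
  })
  gu <- build_overlap_graph(unrel, pipeline_params())
  expect_equal(nrow(gu$edges), 0L)
})

test_that("small components are reported as failed to assemble", {
  truth <- rand_map(80, seed = 42)
  two <- tile_molecules(slice_map(truth, 0, 450000, "t"), n = 2,
                        mol_len = 300000)
  lay <- layout_and_consensus(build_overlap_graph(two, p0), p0)
  expect_equal(length(lay$contigs), 0L)
  expect_equal(length(lay$failed), 1L)
  expect_equal(sort(lay$failed[[1]]), c(1L, 2L))
})

test_that("zero-noise assembly reproduces the source map exactly", {
  truth <- rand_map(110, seed = 43, min_gap = 3500, max_gap = 9000)
  mols <- tile_molecules(truth, n = 50, mol_len = 300000, flip_seed = 99)
  asm <- assemble_molecules(mols, p0)
  expect_equal(length(asm$contigs), 1L)
  cons <- asm$contigs[[1]]
  expect_equal(length(cons$map$positions), length(truth$positions))
  d <- diff(cons$map$positions)
  dt <- diff(truth$positions)
  # the assembly frame may be mirrored; spacings match either way
  expect_true(isTRUE(all.equal(d, dt, tolerance = 1e-6)) ||
                isTRUE(all.equal(rev(d), dt, tolerance = 1e-6)))
  expect_true(all(cons$support <= cons$n_molecules))
})

test_that("refinement extends a truncated consensus back to full length", {
  truth <- rand_map(90, seed = 44, min_gap = 3500, max_gap = 9000)
  mols <- tile_molecules(truth, n = 40, mol_len = 300000)
  lay <- layout_and_consensus(build_overlap_graph(mols, p0), p0)
  cons <- refine_and_extend(lay$contigs[[1]], p0)
  full_n <- length(cons$map$positions)
  # plant a 50-kb truncation
  L <- cons$map$length_bp
  keep <- cons$map$positions <= L - 50000
  cons$map <- label_map(cons$map$id, L - 50000, cons$map$positions[keep])
  cons$support <- cons$support[keep]
  rec <- refine_and_extend(cons, p0)
  expect_equal(length(rec$map$positions), full_n)
  expect_gt(rec$map$length_bp, L - 5000)
})

test_that("merging joins same-haplotype maps and is idempotent", {
  truth <- rand_map(120, seed = 45, min_gap = 3500, max_gap = 9000)
  asm_part <- function(from, to) {
    mols <- tile_molecules(slice_map(truth, from, to, "part"), n = 25,
                           mol_len = 250000)
    assemble_molecules(mols, p0)$contigs[[1]]
  }
  a <- asm_part(0, 450000)
  b <- asm_part(250000, 700000)
  merged <- merge_consensus(list(a, b), p0)
  expect_equal(length(merged), 1L)
  again <- merge_consensus(merged, p0)
  expect_equal(length(again), 1L)
  expect_equal(merged[[1]]$map$positions, again[[1]]$map$positions)
})

test_that("maps of haplotypes differing by an insertion are not merged", {
  set.seed(46)
  base <- cumsum(round(runif(80, 4000, 9000)))
  insertion <- 300000 + cumsum(c(5000, 8000, 7000, 6000, 9000))
  hapA <- label_map("A", max(base) + 5000, base)
  posB <- sort(c(base[base <= 300000], insertion,
                 base[base > 300000] + 45000))
  hapB <- label_map("B", max(posB) + 5000, posB)
  ca <- assemble_molecules(tile_molecules(hapA, n = 25, mol_len = 250000),
                           p0)$contigs[[1]]
  cb <- assemble_molecules(tile_molecules(hapB, n = 25, mol_len = 250000),
                           p0)$contigs[[1]]
  out <- merge_consensus(list(ca, cb), p0)
  expect_equal(length(out), 2L)
})

test_that("a heterozygous terminal-length difference yields two contigs", {
  lib <- default_block_library()
  sc <- cached("sc_ins", scenario_insertion_polymorphism(library = lib))
  asm <- cached("hetasm", {
    mols <- simulate_genome_arm(sc$haps, "major", "minor",
                                pipeline_params(), seed = 31,
                                genome = "G1", arm = "2q")
    assemble_molecules(mols, pipeline_params())
  })
  expect_equal(length(asm$contigs), 2L)
  lens <- sort(vapply(asm$contigs, function(co) co$map$length_bp, 0))
  expect_gt(diff(lens), pipeline_params()$gap_resolution_bp)
  # support never exceeds the number of member molecules
  for (co in asm$contigs)
    expect_true(all(co$support <= co$n_molecules))
})
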