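## End-to-end orchestration: simulate a diploid cohort, assemble each
## genome-arm, anchor and call contigs, cluster haplotypes, detect
## blocks and run the population statistics. One global seed fans out
## to per-stage child seeds so stages are individually reproducible.

#' Simulate one genome-arm's molecules
#'
#' A diploid genome contributes molecules from both alleles, each at
#' half the target coverage.
#'
#' @param haps Named list of haplotype [label_map()]s.
#' @param hap1,hap2 Names of the two alleles.
#' @param params [pipeline_params()].
#' @param seed Integer seed.
#' @param coverage Total target coverage for the genome-arm.
#' @param ... Passed to [simulate_molecules()].
#' @return List of `sim_molecule`s.
#' @export
simulate_genome_arm <- function(haps, hap1, hap2,
                                params = pipeline_params(), seed = 1,
                                coverage = params$min_coverage, ...) {
  m1 <- simulate_molecules(haps[[hap1]], params, seed = seed,
                           coverage = coverage / 2, hap = hap1, ...)
  m2 <- simulate_molecules(haps[[hap2]], params, seed = child_seed(seed, 1),
                           coverage = coverage / 2, hap = hap2, ...)
  mols <- c(m1, m2)
  for (k in seq_along(mols))
    mols[[k]]$map$id <- sprintf("mol%05d", k)
  mols
}

#' Run the full pipeline on a scenario
#'
#' Stages: population sampling, molecule simulation, per-genome-arm
#' assembly, anchoring and arm calls, haplotype clustering and arm
#' summaries, block detection and presence, frequency tables and
#' ANOVA with Bonferroni correction. Deterministic under `seed`.
#'
#' @param scenario A scenario list (see [demo_scenario()]): `library`,
#'   `sizes`, `arms` (each with `ref_arm`, `haps`, `freqs`), optional
#'   `groups`.
#' @param seed Integer master seed.
#' @param params [pipeline_params()].
#' @param out_dir Optional directory for TSV outputs.
#' @param telomere_labeling Simulate telomere end labels.
#' @return List: `calls`, `arm_summary`, `hits`, `presence`,
#'   `freq_tables`, `anova`, `assignments`, `manifest`.
#' @export
run_pipeline <- function(scenario, seed = 1, params = pipeline_params(),
                         out_dir = NULL, telomere_labeling = TRUE) {
  pop <- population_spec(scenario$sizes,
                         lapply(scenario$arms, `[[`, "freqs"))
  assign <- sample_population(pop, child_seed(seed, 1))
  ref_arms <- lapply(scenario$arms, `[[`, "ref_arm")
  calls <- list(); maps <- list(); hits <- list()
  failed <- stats::setNames(rep(0L, length(scenario$arms)),
                            names(scenario$arms))
  patterns <- block_patterns(scenario$library)
  sim_counter <- 100L
  for (r in seq_len(nrow(assign))) {
    row <- assign[r, ]
    armdef <- scenario$arms[[row$arm]]
    sim_counter <- sim_counter + 1L
    mols <- simulate_genome_arm(armdef$haps, row$hap1, row$hap2, params,
                                seed = child_seed(seed, sim_counter),
                                genome = row$genome, arm = row$arm,
                                telomere_labeling = telomere_labeling)
    asm <- assemble_molecules(mols, params)
    n_anchored <- 0L
    for (cons in asm$contigs) {
      anc <- anchor_to_arm(cons, ref_arms, params)
      if (is.null(anc)) next
      arm <- ref_arms[[anc$arm]]
      ext <- measure_extension(anc, arm, params)
      gaecall <- assess_gap(anc, arm, ext, params)
      tel <- confirm_telomere_anchored(cons, anc, params)
      n_anchored <- n_anchored + 1L
      contig_id <- sprintf("%s_%s_%s", row$genome, row$arm, cons$map$id)
      member_haps <- vapply(cons$mols, function(m) as.character(m$hap), "")
      calls[[length(calls) + 1L]] <- data.frame(
        genome = row$genome, superpop = row$superpop, arm = anc$arm,
        contig = contig_id, anchored = TRUE,
        extension_bp = ext$extension_bp,
        extension_called_bp = ext$extension_called_bp,
        gap_correction_bp = ext$gap_correction_bp,
        gap_correction_called_bp = ext$gap_correction_called_bp,
        gap_assessment = gaecall, telomere_confirmed = tel,
        n_molecules = cons$n_molecules,
        truth_hap = names(which.max(table(member_haps))))
      maps[[contig_id]] <- anc$map
      h <- detect_blocks(anc$map, patterns, params)
      if (nrow(h)) {
        h$genome <- row$genome; h$arm <- anc$arm; h$contig <- contig_id
        hits[[length(hits) + 1L]] <- h
      }
    }
    if (n_anchored == 0L) failed[row$arm] <- failed[row$arm] + 1L
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(genome = character(0), arm = character(0))
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(block = character(0), genome = character(0),
               arm = character(0))
  # haplotype clustering and arm summaries
  calls$cluster <- NA_integer_
  summaries <- list()
  for (arm in names(scenario$arms)) {
    idx <- which(calls$arm == arm)
    if (length(idx)) {
      cl <- cluster_haplotypes(calls[idx, , drop = FALSE],
                               maps[calls$contig[idx]], params)
      calls$cluster[idx] <- cl
    }
    summaries[[arm]] <- summarize_arm(calls[idx, , drop = FALSE], arm,
                                      n_failed = failed[[arm]], params)
  }
  arm_summary <- do.call(rbind, summaries)
  # block presence and population statistics
  cohort <- unique(calls[, c("genome", "superpop", "arm")])
  presence <- presence_matrix(hits, cohort,
                              blocks = names(patterns),
                              groups = scenario$groups %||% list())
  presence$superpop <- cohort$superpop[match(paste(presence$genome, presence$arm),
                                             paste(cohort$genome, cohort$arm))]
  block_cols <- setdiff(names(presence), c("genome", "arm", "superpop"))
  freq_tables <- lapply(stats::setNames(block_cols, block_cols),
                        function(b) block_frequency_table(presence, b))
  anova_rows <- list()
  for (b in block_cols) {
    for (arm in unique(presence$arm)) {
      sub <- presence[presence$arm == arm, ]
      if (nrow(sub) < 4 || length(unique(sub$superpop)) < 2) next
      if (any(table(sub$superpop) < 2)) next
      anova_rows[[length(anova_rows) + 1L]] <-
        anova_by_superpop(sub[[b]], sub$superpop, block = b, arm = arm)
    }
  }
  anova <- if (length(anova_rows)) {
    av <- do.call(rbind, anova_rows)
    do.call(rbind, lapply(split(av, av$block), bonferroni_adjust))
  } else data.frame()
  manifest <- list(seed = seed, n_genomes = sum(scenario$sizes),
                   arms = names(scenario$arms),
                   n_calls = nrow(calls), n_failed = as.list(failed),
                   params = unclass(params)[c("fp_rate", "fn_rate",
                                              "min_molecule_bp",
                                              "min_coverage",
                                              "gap_resolution_bp")])
  res <- list(calls = calls, arm_summary = arm_summary, hits = hits,
              presence = presence, freq_tables = freq_tables,
              anova = anova, assignments = assign, maps = maps,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, seed)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

confirm_telomere_anchored <- function(cons, anc, params) {
  confirm_telomere(cons, params, telomere_right = !anc$flipped)
}

write_tsv_seeded <- function(d, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_seeded(res$calls, file.path(out_dir, "calls.tsv"), seed)
  write_tsv_seeded(res$arm_summary, file.path(out_dir, "arm_summary.tsv"), seed)
  write_tsv_seeded(res$presence, file.path(out_dir, "presence.tsv"), seed)
  if (nrow(res$anova))
    write_tsv_seeded(res$anova, file.path(out_dir, "anova.tsv"), seed)
  for (b in names(res$freq_tables))
    write_tsv_seeded(res$freq_tables[[b]],
                     file.path(out_dir, sprintf("freq_%s.tsv", b)), seed)
  invisible(out_dir)
}

#' Compare pipeline calls with simulation truth
#'
#' Per arm: adjusted Rand agreement between called haplotype clusters
#' and true haplotype labels, mean absolute extension error, the
#' gap-assessment tally, and block presence precision/recall against
#' the truth composition of each contig's haplotype.
#'
#' @param result A [run_pipeline()] result.
#' @param scenario The scenario it was run on.
#' @return data.frame with one row per arm.
#' @export
evaluate_against_truth <- function(result, scenario) {
  calls <- result$calls
  out <- list()
  for (arm in unique(calls$arm)) {
    sub <- calls[calls$arm == arm, ]
    ari <- if (nrow(sub) > 1 && length(unique(sub$truth_hap)) >= 1)
      mclust::adjustedRandIndex(sub$cluster, sub$truth_hap) else NA_real_
    if (nrow(sub) > 1 && (length(unique(sub$truth_hap)) == 1) &&
        length(unique(sub$cluster)) == 1)
      ari <- 1  # single class on both sides: perfect agreement
    true_ext <- vapply(sub$truth_hap, function(h) {
      sp <- attr(scenario$arms[[arm]]$haps[[h]], "spec")
      if (is.null(sp)) NA_real_ else sp$extension_bp
    }, 0)
    ext_err <- mean(abs(sub$extension_called_bp - true_ext), na.rm = TRUE)
    # block recall/precision at contig level
    tp <- fp <- fn <- 0
    for (r in seq_len(nrow(sub))) {
      truth_blocks <- unique(attr(scenario$arms[[arm]]$haps[[sub$truth_hap[r]]],
                                  "truth")$block)
      truth_blocks <- intersect(truth_blocks,
                                names(block_patterns(scenario$library)))
      called <- unique(result$hits$block[result$hits$contig == sub$contig[r]])
      tp <- tp + length(intersect(called, truth_blocks))
      fp <- fp + length(setdiff(called, truth_blocks))
      fn <- fn + length(setdiff(truth_blocks, called))
    }
    out[[arm]] <- data.frame(
      arm = arm, n_contigs = nrow(sub), cluster_agreement = ari,
      mean_extension_error_kb = ext_err / 1000,
      block_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      block_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  do.call(rbind, out)
}
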