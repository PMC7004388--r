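#' Pipeline parameters
#'
#' Bundles every tunable knob of the simulation / assembly / calling
#' pipeline with defaults matching the study design the package
#' emulates: Nt.BspQI-style labelling with 10% false-positive and 10%
#' false-negative label error, molecules longer than 150 kb at a mean
#' coverage depth of 60x, 500-kb subtelomere windows, and a 10-kb
#' reporting resolution below which terminal length differences are not
#' called.
#'
#' @param fp_rate Fraction of observed labels that are spurious
#'   (extra nicks at wrong sites). Default 0.10.
#' @param fn_rate Probability that a true nick site goes unlabelled.
#'   Default 0.10.
#' @param min_molecule_bp Minimum single-molecule length kept, bp.
#' @param mean_molecule_bp Mean molecule length of the shifted
#'   exponential length model, bp.
#' @param min_coverage Target mean coverage depth per haplotype map.
#' @param window_bp Subtelomere window size, bp (distal 500 kb).
#' @param gap_resolution_bp Reporting resolution for terminal length
#'   differences; calls smaller than this are reported as 0.
#' @param variability_threshold Minor-haplotype share above which an
#'   arm is classified highly variable (strict inequality).
#' @param optical_resolution_bp Minimum separation at which two labels
#'   are resolved; closer labels merge to their midpoint.
#' @param inp_distance_bp Maximum distance between opposing-strand nick
#'   sites for the pair to count as an inverted nick pair (INP).
#' @param sizing_cv Multiplicative sizing-error coefficient of
#'   variation per inter-label interval.
#' @param jitter_bp Additive per-label Gaussian position error SD, bp.
#' @param p_break Probability that a molecule spanning an INP site
#'   breaks there.
#' @param match_reward Per-matched-label reward of the alignment score.
#' @param fp_penalty,fn_penalty Per-event penalties for unmatched
#'   query / target labels; defaults are -log of the error rates.
#' @param max_skip Maximum consecutive unmatched labels per side within
#'   an alignment chunk.
#' @param min_aligned_labels Minimum matched labels for an alignment
#'   (or overlap-graph edge, or arm anchor) to be accepted.
#' @param min_score Minimum alignment score for acceptance; calibrated
#'   so chance alignments of unrelated maps are rejected (see the
#'   methods vignette).
#' @param support_fraction Fraction of local molecule depth a candidate
#'   consensus label must reach to be kept.
#' @param anchor_margin Factor by which the best arm's anchoring score
#'   must exceed the second best.
#' @param telomere_confirm_k Number of telomere-labelled molecule ends
#'   required to confirm a contig terminus.
#' @param block_match_fraction Minimum fraction of a block pattern's
#'   labels that must match for a block hit.
#' @param block_min_mean_score Minimum mean per-label score of a block
#'   hit.
#' @param merge_span_fraction Fraction of labels inside the implied
#'   shared span that must match for two consensus maps to merge.
#' @param ... Additional named values stored verbatim (reserved).
#'
#' @return A list of class `subtelo_params`.
#' @export
pipeline_params <- function(fp_rate = 0.10,
                            fn_rate = 0.10,
                            min_molecule_bp = 150000,
                            mean_molecule_bp = 300000,
                            min_coverage = 60,
                            window_bp = 500000,
                            gap_resolution_bp = 10000,
                            variability_threshold = 0.10,
                            optical_resolution_bp = 1500,
                            inp_distance_bp = 1000,
                            sizing_cv = 0.02,
                            jitter_bp = 300,
                            p_break = 0.9,
                            match_reward = 3,
                            fp_penalty = -log(max(fp_rate, 1e-6)),
                            fn_penalty = -log(max(fn_rate, 1e-6)),
                            max_skip = 3,
                            min_aligned_labels = 9,
                            min_score = 15,
                            support_fraction = 0.3,
                            anchor_margin = 1.2,
                            telomere_confirm_k = 3,
                            block_match_fraction = 0.75,
                            block_min_mean_score = 2,
                            merge_span_fraction = 0.8,
                            ...) {
  p <- c(as.list(environment()), list(...))
  rates <- c(p$fp_rate, p$fn_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            p$min_molecule_bp > 0, p$mean_molecule_bp >= p$min_molecule_bp,
            p$min_coverage > 0, p$window_bp > 0,
            p$gap_resolution_bp > 0, p$optical_resolution_bp > 0,
            p$fp_penalty >= 0, p$fn_penalty >= 0, p$max_skip >= 1,
            p$variability_threshold >= 0, p$variability_threshold <= 1)
  structure(p, class = "subtelo_params")
}

## deterministic child-seed derivation so stages can be rerun in
## isolation; keeps values inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}
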