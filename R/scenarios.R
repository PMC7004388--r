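## Ready-made simulation scenarios emulating the structural situations
## the pipeline is built to call: a terminal extension beyond the
## reference sequenced end, an over-estimated telomere-adjacent N-gap,
## and a terminal insertion polymorphism segregating in a diploid
## cohort.

## choose a prefix of candidate blocks whose composed length (junction
## + pattern span) fits inside target_bp, and the terminal pad that
## lands the composition exactly on target_bp
plan_extension_blocks <- function(target_bp, library,
                                  candidates = names(library),
                                  junction_bp = 6000, min_pad = 4000) {
  picked <- character(0)
  used <- 0
  for (b in candidates) {
    span <- sum(library[[b]]$label_spacings)
    if (used + junction_bp + span + min_pad <= target_bp) {
      picked <- c(picked, b)
      used <- used + junction_bp + span
    }
  }
  list(blocks = picked, pad = target_bp - used)
}

#' Scenario: haplotype extending beyond the reference sequenced end
#'
#' A q-arm reference whose sequence ends `terminal_gap_bp` short of
#' the annotated chromosome end, and a true haplotype whose telomere
#' lies `extension_bp` beyond the sequenced end, the extra DNA made of
#' paralogy blocks. Emulates arms where genome maps carry large
#' telomere-ward extensions of duplicated material.
#'
#' @param extension_bp True extension beyond the sequenced reference
#'   end (default 130 kb).
#' @param terminal_gap_bp Terminal N-gap annotated on the reference
#'   (default 60 kb).
#' @param arm Arm name.
#' @param library Block library.
#' @return List: `ref_arm`, `true_map` (with truth attributes),
#'   `specs`.
#' @export
scenario_terminal_extension <- function(extension_bp = 130000,
                                        terminal_gap_bp = 60000,
                                        arm = "3q",
                                        library = default_block_library()) {
  ref_spec <- haplotype_spec("ref", arm, block_order = c("B6", "B7"),
                             terminal_gap_bp = terminal_gap_bp)
  plan <- plan_extension_blocks(extension_bp + ref_spec$terminal_pad_bp,
                                library,
                                candidates = c("B1", "B2", "B3", "B4", "B5"))
  true_spec <- haplotype_spec("extended", arm,
                              block_order = c("B6", "B7", plan$blocks),
                              terminal_pad_bp = plan$pad,
                              extension_bp = extension_bp)
  ref_arm <- build_reference_arm(ref_spec, library)
  true_map <- compose_haplotype(true_spec, library)
  stopifnot(true_map$length_bp - ref_arm$tel_end_bp == extension_bp)
  list(ref_arm = ref_arm, true_map = true_map,
       specs = list(ref = ref_spec, true = true_spec))
}

#' Scenario: over-estimated telomere-adjacent gap
#'
#' The reference pads `gap_bp` of N beyond its sequenced end, but the
#' true haplotype's telomere sits exactly at the sequenced end: none
#' of the molecules extend into the gap, and telomere end labels
#' confirm the terminus, so the gap should be deleted (negative gap
#' correction of magnitude `gap_bp`).
#'
#' @param gap_bp Annotated terminal N-gap size (default 110 kb).
#' @param arm Arm name.
#' @param library Block library.
#' @return List: `ref_arm`, `true_map`, `specs`.
#' @export
scenario_gap_overestimate <- function(gap_bp = 110000, arm = "18q",
                                      library = default_block_library()) {
  ref_spec <- haplotype_spec("ref", arm, block_order = c("B6", "B8"),
                             terminal_gap_bp = gap_bp)
  ref_arm <- build_reference_arm(ref_spec, library)
  true_spec <- haplotype_spec("gapless", arm, block_order = c("B6", "B8"),
                              extension_bp = 0)
  true_map <- compose_haplotype(true_spec, library)
  stopifnot(true_map$length_bp == ref_arm$tel_end_bp)
  list(ref_arm = ref_arm, true_map = true_map,
       specs = list(ref = ref_spec, true = true_spec))
}

#' Scenario: terminal insertion polymorphism in a diploid cohort
#'
#' Two haplotypes of one arm: the major matches the reference; the
#' minor carries a terminal insertion of `insert_bp` more DNA (a
#' paralogy block plus pad) beyond the major's telomere. Genomes draw
#' two alleles per arm at `minor_freq`.
#'
#' @param insert_bp Terminal insertion length (default 45 kb).
#' @param minor_freq Minor haplotype frequency (default 0.35).
#' @param arm Arm name.
#' @param library Block library.
#' @return List: `ref_arm`, `haps` (named list of maps), `freqs`
#'   (per-superpop frequency matrix), `specs`.
#' @export
scenario_insertion_polymorphism <- function(insert_bp = 45000,
                                            minor_freq = 0.35,
                                            arm = "2q",
                                            library = default_block_library()) {
  ref_spec <- haplotype_spec("major", arm, block_order = c("B7", "B4"),
                             terminal_gap_bp = 10000)
  plan <- plan_extension_blocks(insert_bp + ref_spec$terminal_pad_bp,
                                library, candidates = c("B8"))
  minor_spec <- haplotype_spec("minor", arm,
                               block_order = c("B7", "B4", plan$blocks),
                               terminal_pad_bp = plan$pad,
                               extension_bp = insert_bp)
  ref_arm <- build_reference_arm(ref_spec, library)
  major <- compose_haplotype(ref_spec, library)
  minor <- compose_haplotype(minor_spec, library)
  stopifnot(minor$length_bp - major$length_bp == insert_bp)
  pops <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  freqs <- matrix(rep(c(1 - minor_freq, minor_freq), each = length(pops)),
                  nrow = length(pops),
                  dimnames = list(pops, c("major", "minor")))
  list(ref_arm = ref_arm, haps = list(major = major, minor = minor),
       freqs = freqs, specs = list(ref = ref_spec, minor = minor_spec))
}

#' Demo scenario: two arms with a population-structured block
#'
#' Two q arms sharing paralogy blocks but with distinct 1-copy anchor
#' patterns. On the second arm, block B5 rides on a carrier haplotype
#' that is common in AFR and rare elsewhere, giving the downstream
#' ANOVA something to find; the first arm carries B5 at similar
#' frequency everywhere.
#'
#' @param sizes Super-population sizes of the simulated cohort; the
#'   default is a scaled-down cohort that keeps all five groups.
#' @param afr_freq,other_freq Carrier frequencies of the B5 haplotype
#'   on the structured arm.
#' @param library Block library.
#' @return A scenario list consumable by [run_pipeline()].
#' @export
demo_scenario <- function(sizes = c(AFR = 4, AMR = 3, EAS = 3,
                                    EUR = 3, SAS = 3),
                          afr_freq = 0.9, other_freq = 0.15,
                          library = default_block_library()) {
  mk_arm <- function(arm, with_freqs) {
    ref_spec <- haplotype_spec("plain", arm, block_order = c("B6"),
                               terminal_gap_bp = 10000,
                               onecopy_bp = 250000)
    b5_spec <- haplotype_spec("b5carrier", arm, block_order = c("B6", "B5"),
                              onecopy_bp = 250000)
    ref_arm <- build_reference_arm(ref_spec, library)
    plain <- compose_haplotype(ref_spec, library)
    carrier <- compose_haplotype(b5_spec, library)
    # record the carrier's true extension beyond the sequenced end
    sp <- attr(carrier, "spec")
    sp$extension_bp <- carrier$length_bp - ref_arm$tel_end_bp
    attr(carrier, "spec") <- sp
    list(ref_arm = ref_arm,
         haps = list(plain = plain, b5carrier = carrier),
         freqs = with_freqs,
         specs = list(ref = ref_spec, b5carrier = sp))
  }
  pops <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  even <- matrix(rep(c(0.5, 0.5), each = 5), nrow = 5,
                 dimnames = list(pops, c("plain", "b5carrier")))
  structured <- cbind(plain = c(1 - afr_freq,
                                rep(1 - other_freq, 4)),
                      b5carrier = c(afr_freq, rep(other_freq, 4)))
  rownames(structured) <- pops
  list(library = library,
       sizes = sizes,
       arms = list("15q" = mk_arm("15q", even),
                   "16q" = mk_arm("16q", structured)),
       groups = list("B1-2" = c("B1", "B2")))
}
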