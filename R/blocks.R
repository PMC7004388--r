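## Paralogy-block detection on consensus maps by nick-pattern matching.
## Blocks are recognised purely by the spacing pattern of their nick
## sites; small blocks that carry too few sites to stand alone are
## analysed as fixed, named groups.

#' Block patterns and groups
#'
#' Converts a block library into detectable patterns. Patterns with
#' fewer than 3 labels cannot be detected alone and are excluded from
#' standalone detection (use groups for them).
#'
#' @param library Named list of [block_spec()]s.
#' @return Named list of pattern [label_map()]s.
#' @export
block_patterns <- function(library = default_block_library()) {
  pats <- lapply(library, function(b) {
    pos <- cumsum(c(0, b$label_spacings))
    if (length(pos) < 3) return(NULL)
    label_map(b$name, sum(b$label_spacings) + 1, pos)
  })
  Filter(Negate(is.null), pats)
}

#' Detect paralogy blocks on a label map
#'
#' Fit-aligns each pattern (both orientations, repeatedly with already
#' matched labels masked) and reports non-overlapping hits whose
#' matched label fraction reaches `block_match_fraction` and whose
#' mean per-label score reaches `block_min_mean_score`; overlaps are
#' resolved greedily by score with deterministic ties (leftmost, then
#' block name).
#'
#' @param map A [label_map()] (e.g. a consensus map's map).
#' @param patterns Named list from [block_patterns()].
#' @param params [pipeline_params()].
#' @return data.frame of hits: `block`, `map`, `start`, `end`,
#'   `orientation`, `score`, `matched_fraction`.
#' @export
detect_blocks <- function(map, patterns = block_patterns(),
                          params = pipeline_params()) {
  empty <- data.frame(block = character(0), map = character(0),
                      start = numeric(0), end = numeric(0),
                      orientation = character(0), score = numeric(0),
                      matched_fraction = numeric(0))
  if (!length(map$positions)) return(empty)
  hits <- list()
  for (pat in patterns) {
    npat <- length(pat$positions)
    avail <- rep(TRUE, length(map$positions))
    repeat {
      sub_idx <- which(avail)
      if (length(sub_idx) < ceiling(params$block_match_fraction * npat)) break
      sub <- label_map(map$id, map$length_bp, map$positions[sub_idx])
      a <- align_fit(pat, sub, params,
                     min_aligned = ceiling(params$block_match_fraction * npat),
                     min_score = params$block_min_mean_score *
                       ceiling(params$block_match_fraction * npat))
      if (is.null(a)) break
      frac <- a$n_pairs / npat
      ti_full <- sub_idx[a$pairs[, "ti"]]
      if (frac >= params$block_match_fraction &&
          a$score / a$n_pairs >= params$block_min_mean_score) {
        tpos <- map$positions[ti_full]
        hits[[length(hits) + 1L]] <-
          data.frame(block = pat$id, map = map$id,
                     start = min(tpos), end = max(tpos),
                     orientation = a$orientation, score = a$score,
                     matched_fraction = frac)
      }
      avail[ti_full] <- FALSE
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start, h$block), , drop = FALSE]
  keep <- logical(nrow(h))
  taken <- NULL
  for (k in seq_len(nrow(h))) {
    ov <- !is.null(taken) &&
      any(h$start[k] < taken[, 2] & h$end[k] > taken[, 1])
    if (!ov) {
      keep[k] <- TRUE
      taken <- rbind(taken, c(h$start[k], h$end[k]))
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Block presence matrix across a cohort
#'
#' Presence of a block (or any member of its named group) on any
#' anchored contig of a genome-arm.
#'
#' @param hits data.frame of block hits augmented with `genome` and
#'   `arm` columns.
#' @param cohort data.frame with one row per genome-arm to score
#'   (columns `genome`, `arm`; typically every genome-arm with at
#'   least one anchored contig).
#' @param blocks Character vector of block names to score.
#' @param groups Named list mapping group names to member block names
#'   (e.g. `list("B1-2" = c("B1", "B2"))`).
#' @return data.frame: `genome`, `arm`, one logical column per block /
#'   group.
#' @export
presence_matrix <- function(hits, cohort, blocks = NULL,
                            groups = list()) {
  if (is.null(blocks))
    blocks <- sort(unique(hits$block))
  out <- cohort[, c("genome", "arm")]
  key <- paste(out$genome, out$arm)
  for (b in blocks) {
    hb <- hits[hits$block == b, , drop = FALSE]
    out[[b]] <- key %in% paste(hb$genome, hb$arm)
  }
  for (g in names(groups)) {
    hb <- hits[hits$block %in% groups[[g]], , drop = FALSE]
    out[[g]] <- key %in% paste(hb$genome, hb$arm)
  }
  out
}

#' Ordered block signature of one map
#'
#' Hits sorted by position, names joined with orientation marks, e.g.
#' `"B1(+),B3(-)"`; mirroring the map mirrors the signature and flips
#' orientations.
#'
#' @param hits data.frame of block hits on one map.
#' @return Character scalar.
#' @export
block_order_signature <- function(hits) {
  if (!nrow(hits)) return("")
  h <- hits[order(hits$start), , drop = FALSE]
  paste(sprintf("%s(%s)", h$block, h$orientation), collapse = ",")
}
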