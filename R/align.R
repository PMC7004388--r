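#' Score one alignment chunk
#'
#' A chunk extends an alignment by one matched label pair, skipping
#' `nq_skipped` query labels and `nr_skipped` target labels since the
#' previous matched pair. Its score is
#' \deqn{r - \frac{(d_q - d_r)^2}{2(\mathrm{cv}^2 d_r^2 + 2\,\mathrm{jit}^2)}
#'       - n_q\,\mathrm{fp} - n_r\,\mathrm{fn}}
#' where \eqn{d_q, d_r} are the query and target interval lengths.
#' Unmatched query labels are penalised like false-positive labels,
#' unmatched target labels like missed (false-negative) ones.
#'
#' @param dq,dr Query and target inter-label distances, bp (> 0).
#' @param nq_skipped,nr_skipped Labels skipped on each side.
#' @param params [pipeline_params()].
#' @return Numeric chunk score.
#' @export
chunk_score <- function(dq, dr, nq_skipped = 0, nr_skipped = 0,
                        params = pipeline_params()) {
  stopifnot(dq > 0, dr > 0)
  v <- params$sizing_cv^2 * dr^2 + 2 * params$jitter_bp^2
  params$match_reward - (dq - dr)^2 / (2 * v) -
    nq_skipped * params$fp_penalty - nr_skipped * params$fn_penalty
}

## low-level single-orientation DP; mode "fit" penalises unmatched query
## end labels, mode "overlap" leaves both maps' ends free
dp_align <- function(qpos, tpos, params, mode = c("fit", "overlap")) {
  mode <- match.arg(mode)
  .dp_align_cpp(as.numeric(qpos), as.numeric(tpos),
                params$match_reward, params$fp_penalty, params$fn_penalty,
                params$sizing_cv, params$jitter_bp,
                as.integer(params$max_skip),
                if (mode == "fit") 0L else 1L)
}

new_alignment <- function(query, target, orientation, qi, ti, score) {
  qpos <- if (orientation == "+") query$positions else
    rev(query$length_bp - 1 - query$positions)
  pos_q <- qpos[qi]
  pos_t <- target$positions[ti]
  qi_orig <- if (orientation == "+") qi else length(query$positions) + 1L - qi
  structure(list(
    query = query$id, target = target$id, orientation = orientation,
    pairs = cbind(qi = qi_orig, ti = ti),
    n_pairs = length(qi), score = score,
    offset = if (length(qi)) mean(pos_t - pos_q) else NA_real_,
    query_range = if (length(qi)) range(pos_q) else c(NA, NA),
    target_range = if (length(ti)) range(pos_t) else c(NA, NA)),
    class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s ~ %s (%s): %d pairs, score %.3f, offset %.0f\n",
              x$query, x$target, x$orientation, x$n_pairs, x$score, x$offset))
  invisible(x)
}

align_both_orientations <- function(query, target, params, mode) {
  res <- list()
  for (ori in c("+", "-")) {
    qpos <- if (ori == "+") query$positions else
      rev(query$length_bp - 1 - query$positions)
    r <- dp_align(qpos, target$positions, params, mode)
    res[[ori]] <- new_alignment(query, target, ori, r$qi, r$ti, r$score)
  }
  sp <- round(res[["+"]]$score, 9); sm <- round(res[["-"]]$score, 9)
  if (sp > sm) return(res[["+"]])
  if (sm > sp) return(res[["-"]])
  # tie: lowest target offset of the aligned interval, then '+'
  op <- res[["+"]]$target_range[1]; om <- res[["-"]]$target_range[1]
  if (!is.na(om) && !is.na(op) && om < op) res[["-"]] else res[["+"]]
}

accept_alignment <- function(aln, params,
                             min_aligned = params$min_aligned_labels,
                             min_score = params$min_score) {
  if (is.null(aln)) return(NULL)
  if (aln$n_pairs < min_aligned || aln$score < min_score) NULL else aln
}

#' Fit-align a query map into a target map
#'
#' Best-scoring alignment that is global in the query (every unmatched
#' query label is penalised) and local in the target, searched over
#' both orientations by dynamic programming with at most
#' `params$max_skip` consecutive unmatched labels per side within a
#' chunk. Ties are broken toward the lowest target offset, then the
#' `"+"` orientation.
#'
#' @param query,target [label_map()]s (nonempty).
#' @param params [pipeline_params()].
#' @param min_aligned,min_score Acceptance thresholds; the alignment is
#'   dropped (`NULL`) below either.
#' @return A `map_alignment` or `NULL`.
#' @export
align_fit <- function(query, target, params = pipeline_params(),
                      min_aligned = params$min_aligned_labels,
                      min_score = params$min_score) {
  if (!length(query$positions) || !length(target$positions)) return(NULL)
  accept_alignment(align_both_orientations(query, target, params, "fit"),
                   params, min_aligned, min_score)
}

#' Overlap-align two maps (dovetail)
#'
#' Best suffix-prefix style alignment with both maps' ends free;
#' unmatched labels between matched pairs are penalised as in
#' [align_fit()]. The returned `offset` is the signed position of the
#' query's origin in target coordinates (after orientation).
#'
#' @inheritParams align_fit
#' @return A `map_alignment` or `NULL`.
#' @export
align_overlap <- function(query, target, params = pipeline_params(),
                          min_aligned = params$min_aligned_labels,
                          min_score = params$min_score) {
  if (!length(query$positions) || !length(target$positions)) return(NULL)
  accept_alignment(align_both_orientations(query, target, params, "overlap"),
                   params, min_aligned, min_score)
}

#' Dump alignments as a TSV-ready data.frame
#'
#' @param alignments List of `map_alignment` objects (NULLs dropped).
#' @return data.frame with columns query, target, orientation, offset,
#'   score, score_per_label, n_pairs.
#' @export
alignment_table <- function(alignments) {
  alignments <- Filter(Negate(is.null), alignments)
  do.call(rbind, lapply(alignments, function(a)
    data.frame(query = a$query, target = a$target,
               orientation = a$orientation, offset = a$offset,
               score = a$score, score_per_label = a$score / max(1, a$n_pairs),
               n_pairs = a$n_pairs)))
}
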