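## Anchoring consensus maps to reference arms and calling per-arm
## structure: telomeric extensions, telomere-adjacent gap corrections,
## telomere confirmation, INP fragility, haplotype clustering and the
## High/Low variability classification.

#' Anchor a consensus map to its chromosome arm
#'
#' The contig is aligned to every candidate arm (ends free, both
#' orientations). Assignment requires the best arm's alignment to
#' place at least `min_aligned_labels` matched labels inside the arm's
#' 1-copy interval and to beat the second-best arm's score by the
#' configured margin; otherwise the contig is reported unanchored.
#' The returned alignment is normalised so the contig reads
#' telomere-distal-increasing, like the reference.
#'
#' @param contig A `consensus_map` (or bare [label_map()]).
#' @param arms List of [reference_arm()]s.
#' @param params [pipeline_params()].
#' @return List with `arm`, `alignment`, `map` (the oriented contig
#'   map), or `NULL` if unanchored/ambiguous.
#' @export
anchor_to_arm <- function(contig, arms, params = pipeline_params()) {
  cmap <- if (inherits(contig, "consensus_map")) contig$map else contig
  scores <- rep(-Inf, length(arms))
  alns <- vector("list", length(arms))
  for (k in seq_along(arms)) {
    a <- align_overlap(cmap, arms[[k]]$map, params,
                       min_aligned = params$min_aligned_labels,
                       min_score = params$min_score)
    if (is.null(a)) next
    oc <- arms[[k]]$onecopy_interval
    rpos <- arms[[k]]$map$positions[a$pairs[, "ti"]]
    if (sum(rpos >= oc[1] & rpos < oc[2]) < params$min_aligned_labels) next
    scores[k] <- a$score
    alns[[k]] <- a
  }
  if (!any(is.finite(scores))) return(NULL)
  o <- order(-scores)
  best <- o[1]
  if (length(arms) > 1 && is.finite(scores[o[2]]) &&
      scores[best] < params$anchor_margin * scores[o[2]])
    return(NULL)
  a <- alns[[best]]
  omap <- oriented_map(cmap, a$orientation == "-")
  if (a$orientation == "-") {
    a$pairs <- cbind(qi = length(cmap$positions) + 1L - a$pairs[, "qi"],
                     ti = a$pairs[, "ti"])
    a$orientation <- "+"
  }
  list(arm = arms[[best]]$arm, alignment = a, map = omap,
       flipped = !identical(omap$positions, cmap$positions))
}

## affine (scale + offset) projection of a contig coordinate into
## reference coordinates through matched label pairs; a consensus map
## inherits its backbone molecules' overall sizing error, which a pure
## offset fit would propagate into the terminus
affine_fit <- function(qpos, rpos) {
  if (length(qpos) >= 5 && stats::var(qpos) > 0) {
    b <- stats::cov(qpos, rpos) / stats::var(qpos)
    if (b > 0.9 && b < 1.1)
      return(c(a = mean(rpos) - b * mean(qpos), b = b))
  }
  c(a = mean(rpos - qpos), b = 1)
}

project_affine <- function(qpos, rpos, x) {
  f <- affine_fit(qpos, rpos)
  f[["a"]] + f[["b"]] * x
}

#' Measure the telomeric extension of an anchored contig
#'
#' Projects the contig's telomeric terminus into reference coordinates
#' through the alignment's offset fit and reports it relative to the
#' end of real (non-N) reference sequence (`tel_end_bp`) and to the
#' annotated chromosome end (`arm_end_bp`). Values are rounded to the
#' reporting resolution; absolute values below it are reported as 0.
#'
#' @param anchor Result of [anchor_to_arm()].
#' @param arm The matching [reference_arm()].
#' @param params [pipeline_params()].
#' @return List: `extension_bp` (raw, vs `tel_end_bp`),
#'   `extension_called_bp` (rounded), `gap_correction_bp` (raw, vs
#'   `arm_end_bp`), `gap_correction_called_bp` (rounded), `no_call`.
#' @export
measure_extension <- function(anchor, arm, params = pipeline_params()) {
  a <- anchor$alignment
  if (is.null(a) || a$n_pairs < 3)
    return(list(extension_bp = NA_real_, extension_called_bp = NA_real_,
                gap_correction_bp = NA_real_,
                gap_correction_called_bp = NA_real_, no_call = TRUE))
  qpos <- anchor$map$positions[a$pairs[, "qi"]]
  rpos <- arm$map$positions[a$pairs[, "ti"]]
  terminus_ref <- project_affine(qpos, rpos, anchor$map$length_bp)
  ext <- terminus_ref - arm$tel_end_bp
  gapcor <- terminus_ref - arm$arm_end_bp
  # below the resolution a call is 0; above it, report at the half-
  # resolution granularity the summary tables use (multiples of 5 kb)
  round_call <- function(x) {
    if (abs(x) < params$gap_resolution_bp) 0
    else round(x / (params$gap_resolution_bp / 2)) * (params$gap_resolution_bp / 2)
  }
  list(extension_bp = ext, extension_called_bp = round_call(ext),
       gap_correction_bp = gapcor,
       gap_correction_called_bp = round_call(gapcor),
       no_call = FALSE)
}

#' Assess the telomere-adjacent reference gap
#'
#' Classifies how an anchored contig relates to the arm's terminal
#' N-gap. `EXTEND`: the contig reaches beyond the annotated chromosome
#' end (insufficient gap). `SUPPORTED`: the contig terminus falls
#' within the gap (or matches a gapless reference end). `DELETE`: the
#' contig ends at or before the gap start although the reference pads
#' further (excessive gap; negative correction). `INACCURATE`: the
#' 1-copy anchor aligns but the distal reference pattern conflicts
#' with the contig. `NO_CALL`: unanchored or unprojectable.
#'
#' @param anchor Result of [anchor_to_arm()] (or `NULL`).
#' @param arm [reference_arm()].
#' @param ext Result of [measure_extension()].
#' @param params [pipeline_params()].
#' @param mismatch_threshold Maximum tolerated fraction of unmatched
#'   distal reference labels before declaring `INACCURATE`.
#' @return Character scalar, one of SUPPORTED, DELETE, EXTEND,
#'   INACCURATE, NO_CALL.
#' @export
assess_gap <- function(anchor, arm, ext, params = pipeline_params(),
                       mismatch_threshold = 0.5) {
  if (is.null(anchor) || isTRUE(ext$no_call)) return("NO_CALL")
  res <- params$gap_resolution_bp
  g <- arm$arm_end_bp - arm$tel_end_bp
  # distal reference pattern agreement (between 1-copy end and tel end)
  oc_end <- arm$onecopy_interval[2]
  distal <- which(arm$map$positions >= oc_end &
                    arm$map$positions < arm$tel_end_bp)
  qpos <- anchor$map$positions[anchor$alignment$pairs[, "qi"]]
  rpos <- arm$map$positions[anchor$alignment$pairs[, "ti"]]
  f <- affine_fit(qpos, rpos)
  contig_ref_span_hi <- f[["a"]] + f[["b"]] * anchor$map$length_bp
  reachable <- distal[arm$map$positions[distal] < contig_ref_span_hi - res]
  if (length(reachable)) {
    # does the contig actually reproduce the distal reference pattern?
    proj <- f[["a"]] + f[["b"]] * anchor$map$positions
    tol <- params$optical_resolution_bp
    near <- vapply(arm$map$positions[reachable], function(rp)
      min(abs(proj - rp)) <= tol, TRUE)
    if (mean(near) < 1 - mismatch_threshold)
      return("INACCURATE")
  }
  if (g <= res) {
    if (ext$extension_called_bp > 0) return("EXTEND")
    if (ext$extension_called_bp < 0) return("DELETE")
    return("SUPPORTED")
  }
  if (ext$gap_correction_called_bp > 0) return("EXTEND")
  if (ext$extension_bp < res) return("DELETE")
  "SUPPORTED"
}

#' Confirm a contig terminus with telomere end labels
#'
#' TRUE when at least `telomere_confirm_k` telomere-labelled member
#' molecules place their labelled end within tolerance of the contig's
#' telomeric terminus (and none place it beyond).
#'
#' @param contig A `consensus_map` with member placements.
#' @param params [pipeline_params()].
#' @param telomere_right Which contig end is telomeric in its own
#'   frame (default right).
#' @return Logical.
#' @export
confirm_telomere <- function(contig, params = pipeline_params(),
                             telomere_right = TRUE) {
  mem <- contig$members
  tel <- mem[mem$tel, , drop = FALSE]
  if (!nrow(tel)) return(FALSE)
  tol <- 2 * params$optical_resolution_bp
  endpos <- ifelse(tel$tel_right, tel$end, tel$start)
  terminus <- if (telomere_right) contig$map$length_bp else 0
  n_at <- sum(abs(endpos - terminus) <= tol)
  # placement noise can push individual labelled ends past the
  # terminus; the telomere is contradicted only when a clear share of
  # them overshoots
  n_beyond <- if (telomere_right) sum(endpos > terminus + 2 * tol)
              else sum(endpos < terminus - 2 * tol)
  n_at >= params$telomere_confirm_k && n_beyond <= 0.1 * length(endpos)
}

#' Scan a stranded reference map for inverted nick pairs
#'
#' Reports every adjacent label pair on opposing strands closer than
#' `inp_distance_bp`: such sites nick both strands nearby, break the
#' duplex during labelling, and make maps fragile.
#'
#' @param ref_map [label_map()] with strand annotation.
#' @param inp_distance_bp Distance threshold, bp.
#' @return data.frame with `position` (midpoint) and `distance`.
#' @export
scan_inp <- function(ref_map, inp_distance_bp = pipeline_params()$inp_distance_bp) {
  if (is.null(ref_map$strands)) stop("ref_map carries no strand annotation")
  p <- ref_map$positions; s <- ref_map$strands
  out <- data.frame(position = numeric(0), distance = numeric(0))
  if (length(p) < 2) return(out)
  d <- diff(p)
  inv <- s[-length(s)] != s[-1]
  hit <- which(inv & d <= inp_distance_bp)
  data.frame(position = (p[hit] + p[hit + 1]) / 2, distance = d[hit])
}

#' Cluster anchored contigs of one arm into haplotypes
#'
#' Single-linkage clustering: two contigs link when their pairwise
#' alignment matches at least `merge_span_fraction` of the labels in
#' the shared span on both maps and their telomeric terminal lengths
#' (registered through the anchoring alignments) differ by less than
#' the reporting resolution. Cluster ids are ordered by size (1 = the
#' major haplotype); ties break toward the cluster whose first contig
#' came first.
#'
#' @param calls data.frame of per-contig calls for one arm (must
#'   contain `extension_bp`).
#' @param maps List of oriented contig [label_map()]s, parallel to
#'   `calls` rows.
#' @param params [pipeline_params()].
#' @return Integer cluster ids, parallel to `calls` rows.
#' @export
cluster_haplotypes <- function(calls, maps, params = pipeline_params()) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) linked[i, i] <- TRUE
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (abs(calls$extension_bp[i] - calls$extension_bp[j]) >=
            params$gap_resolution_bp) next
        a <- align_overlap(maps[[j]], maps[[i]], params)
        if (is.null(a)) next
        off <- a$offset
        Li <- maps[[i]]$length_bp; Lj <- maps[[j]]$length_bp
        lo <- max(0, off); hi <- min(Li, off + Lj)
        jpos <- oriented_map(maps[[j]], a$orientation == "-")$positions + off
        ni <- sum(maps[[i]]$positions >= lo & maps[[i]]$positions <= hi)
        nj <- sum(jpos >= lo & jpos <= hi)
        if (ni == 0 || nj == 0) next
        if (a$n_pairs / ni >= params$merge_span_fraction &&
            a$n_pairs / nj >= params$merge_span_fraction)
          linked[i, j] <- linked[j, i] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  first <- vapply(names(sizes), function(k) min(which(comp == as.integer(k))), 0)
  rank <- order(-as.integer(sizes), first)
  match(comp, as.integer(names(sizes))[rank])
}

#' Classify an arm's structural variability
#'
#' HIGH when the minor haplotypes' combined share of represented
#' contigs strictly exceeds the threshold (default 10%); a minor share
#' of exactly the threshold is LOW.
#'
#' @param cluster_sizes Integer vector of haplotype cluster sizes.
#' @param threshold Minor-share threshold (default
#'   `pipeline_params()$variability_threshold`).
#' @return `"HIGH"` or `"LOW"`.
#' @export
classify_variability <- function(cluster_sizes,
                                 threshold = pipeline_params()$variability_threshold) {
  stopifnot(length(cluster_sizes) >= 1)
  total <- sum(cluster_sizes)
  minor <- total - max(cluster_sizes)
  if (minor / total > threshold) "HIGH" else "LOW"
}

#' Summarise the calls of one arm
#'
#' Aggregates representation, failures, haplotype cluster sizes, the
#' High/Low variability class and extension / gap-correction ranges
#' into one summary row. Every anchored contig counts toward
#' `n_represented`, so a diploid genome with two distinct haplotype
#' contigs contributes twice.
#'
#' @param calls data.frame of per-contig calls for one arm with
#'   columns `cluster`, `extension_called_bp`,
#'   `gap_correction_called_bp`.
#' @param arm Arm name.
#' @param n_failed Number of genomes that failed to assemble a contig.
#' @param params [pipeline_params()].
#' @return One-row data.frame (Table-style summary).
#' @export
summarize_arm <- function(calls, arm = calls$arm[1], n_failed = 0,
                          params = pipeline_params()) {
  if (is.null(calls) || nrow(calls) == 0)
    return(data.frame(arm = arm, n_represented = 0L, n_failed = n_failed,
                      n_clusters = 0L, cluster_sizes = "",
                      variability = "NA",
                      extension_range = "", gap_correction_range = ""))
  sizes <- sort(table(calls$cluster), decreasing = TRUE)
  fmt_range <- function(x) {
    x <- x[!is.na(x)] / 1000
    if (!length(x)) return("")
    if (min(x) == max(x)) sprintf("%g", min(x))
    else sprintf("%g-%g", min(x), max(x))
  }
  data.frame(arm = arm,
             n_represented = nrow(calls),
             n_failed = n_failed,
             n_clusters = length(sizes),
             cluster_sizes = paste(as.integer(sizes), collapse = ","),
             variability = classify_variability(as.integer(sizes),
                                                params$variability_threshold),
             extension_range = fmt_range(calls$extension_called_bp),
             gap_correction_range = fmt_range(calls$gap_correction_called_bp))
}
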