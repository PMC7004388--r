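## Overlap-layout-consensus assembly of single-molecule label maps.
##
## Molecules arrive in unknown orientation; the overlap graph fixes a
## global orientation per connected component (best-score-first union
## find with parity), converts pairwise dovetail offsets into a common
## frame, prunes offset-inconsistent triangles and transitively
## redundant edges, and directs edges left-to-right so each component
## is a DAG.

oriented_map <- function(m, flip) if (flip) reverse_map(m) else m

#' Build the pruned molecule overlap graph
#'
#' All-vs-all dovetail alignments above threshold become edges;
#' orientation-conflicting edges, offset-inconsistent triangles
#' (lowest-score edge dropped) and transitively redundant edges are
#' removed. Offsets are expressed in a per-component global frame.
#'
#' @param molecules List of `sim_molecule` (or bare [label_map()])
#'   objects.
#' @param params [pipeline_params()].
#' @param triangle_tol_bp Offset slack allowed around triangles.
#' @return An `overlap_graph`: edges (`from`, `to`, `offset`, `score`),
#'   per-molecule global flips, component membership.
#' @export
build_overlap_graph <- function(molecules, params = pipeline_params(),
                                triangle_tol_bp = 10000) {
  maps <- lapply(molecules, function(m) if (inherits(m, "label_map")) m else m$map)
  n <- length(maps)
  stopifnot(n >= 1)
  ed <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- align_overlap(maps[[j]], maps[[i]], params)
      if (!is.null(a))
        ed[[length(ed) + 1L]] <-
          data.frame(i = i, j = j, orient = a$orientation,
                     offset = a$offset, score = a$score)
    }
  }
  flips <- rep(FALSE, n)
  if (length(ed)) {
    ed <- do.call(rbind, ed)
    ed <- ed[order(-ed$score, ed$i, ed$j), , drop = FALSE]
    # union-find with parity to fix orientations
    parent <- seq_len(n); parity <- rep(FALSE, n)
    find <- function(x) {
      p <- FALSE
      while (parent[x] != x) { p <- xor(p, parity[x]); x <- parent[x] }
      list(root = x, parity = p)
    }
    keep <- logical(nrow(ed))
    for (k in seq_len(nrow(ed))) {
      o <- ed$orient[k] == "-"
      fi <- find(ed$i[k]); fj <- find(ed$j[k])
      if (fi$root == fj$root) {
        keep[k] <- xor(fi$parity, fj$parity) == o
      } else {
        parent[fj$root] <- fi$root
        parity[fj$root] <- xor(xor(fi$parity, fj$parity), o)
        keep[k] <- TRUE
      }
    }
    ed <- ed[keep, , drop = FALSE]
    for (v in seq_len(n)) flips[v] <- find(v)$parity
    # offsets into the global frame
    off <- numeric(nrow(ed))
    for (k in seq_len(nrow(ed))) {
      i <- ed$i[k]; j <- ed$j[k]
      off[k] <- if (!flips[i]) ed$offset[k]
                else maps[[i]]$length_bp - ed$offset[k] - maps[[j]]$length_bp
    }
    ed$offset <- off
    # triangle consistency
    repeat {
      drop_k <- NA
      key <- paste(ed$i, ed$j)
      idx <- stats::setNames(seq_len(nrow(ed)), key)
      nb <- vector("list", n)
      for (k in seq_len(nrow(ed))) {
        nb[[ed$i[k]]] <- c(nb[[ed$i[k]]], k)
        nb[[ed$j[k]]] <- c(nb[[ed$j[k]]], k)
      }
      eoff <- function(k, from) if (ed$i[k] == from) ed$offset[k] else -ed$offset[k]
      other <- function(k, from) if (ed$i[k] == from) ed$j[k] else ed$i[k]
      for (k in seq_len(nrow(ed))) {
        a <- ed$i[k]; b <- ed$j[k]
        common <- intersect(vapply(nb[[a]], other, 0L, from = a),
                            vapply(nb[[b]], other, 0L, from = b))
        for (c_ in setdiff(common, c(a, b))) {
          k1 <- idx[paste(min(a, c_), max(a, c_))]
          k2 <- idx[paste(min(b, c_), max(b, c_))]
          resid <- abs(eoff(k, a) + eoff(k2, b) - eoff(k1, a))
          if (is.finite(resid) && resid > triangle_tol_bp) {
            trio <- c(k, k1, k2)
            drop_k <- trio[which.min(ed$score[trio])]
            break
          }
        }
        if (!is.na(drop_k)) break
      }
      if (is.na(drop_k)) break
      ed <- ed[-drop_k, , drop = FALSE]
    }
    # direct edges left-to-right
    swap <- ed$offset < 0 | (ed$offset == 0 & ed$i > ed$j)
    from <- ifelse(swap, ed$j, ed$i)
    to <- ifelse(swap, ed$i, ed$j)
    ed <- data.frame(from = from, to = to,
                     offset = abs(ed$offset), score = ed$score)
    # near-zero offset inconsistencies below the triangle tolerance can
    # still direct a cycle; drop a minimum-score feedback arc set
    if (nrow(ed) > 1) {
      g <- igraph::graph_from_data_frame(
        ed[, c("from", "to")], directed = TRUE,
        vertices = data.frame(name = seq_len(n)))
      if (!igraph::is_dag(g)) {
        fas <- igraph::feedback_arc_set(g, weights = ed$score)
        ed <- ed[-as.integer(fas), , drop = FALSE]
        g <- igraph::graph_from_data_frame(
          ed[, c("from", "to")], directed = TRUE,
          vertices = data.frame(name = seq_len(n)))
      }
    }
    # transitive reduction via reachability in topological order
    if (nrow(ed) > 1) {
      topo <- as.integer(names(igraph::topo_sort(g)))
      reach <- matrix(FALSE, n, n)
      out_of <- split(seq_len(nrow(ed)), ed$from)
      for (v in rev(topo)) {
        ks <- out_of[[as.character(v)]]
        for (k in ks) {
          w <- ed$to[k]
          reach[v, w] <- TRUE
          reach[v, ] <- reach[v, ] | reach[w, ]
        }
      }
      redundant <- vapply(seq_len(nrow(ed)), function(k) {
        u <- ed$from[k]; w <- ed$to[k]
        any(vapply(ed$to[out_of[[as.character(u)]]], function(v)
          v != w && reach[v, w], TRUE))
      }, TRUE)
      ed <- ed[!redundant, , drop = FALSE]
    }
  } else {
    ed <- data.frame(from = integer(0), to = integer(0),
                     offset = numeric(0), score = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(ed)) ed[, c("from", "to")] else
      data.frame(from = integer(0), to = integer(0)),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g, mode = "weak")$membership
  structure(list(n = n, edges = ed, flips = flips,
                 components = as.integer(comp), molecules = molecules),
            class = "overlap_graph")
}

## ---- consensus construction -------------------------------------------

consensus_from_placements <- function(members, mols, params, id = "contig") {
  shift <- min(members$offset)
  members$offset <- members$offset - shift
  members$start <- members$offset
  members$end <- members$offset +
    vapply(mols, function(m) m$map$length_bp, 0)
  pooled <- list()
  for (r in seq_len(nrow(members))) {
    om <- oriented_map(mols[[r]]$map, members$flip[r])
    if (length(om$positions))
      pooled[[r]] <- data.frame(pos = om$positions + members$offset[r],
                                mol = r)
  }
  pooled <- if (length(pooled)) do.call(rbind, pooled) else
    data.frame(pos = numeric(0), mol = integer(0))
  lab <- numeric(0); supp <- integer(0)
  if (nrow(pooled)) {
    cl <- pool_clusters(pooled$pos, pooled$mol, params$optical_resolution_bp)
    for (k in seq_len(nrow(cl))) {
      depth <- sum(members$start <= cl$center[k] & members$end >= cl$center[k])
      thr <- max(ceiling(params$support_fraction * depth), min(2L, depth))
      if (cl$support[k] >= thr) {
        lab <- c(lab, round(cl$center[k])); supp <- c(supp, cl$support[k])
      }
    }
  }
  len <- max(members$end)
  keep <- lab >= 0 & lab < len
  lab <- lab[keep]; supp <- supp[keep]
  o <- order(lab)
  lab <- lab[o]; supp <- supp[o]
  dup <- duplicated(lab)
  tel_right <- mapply(function(m, f) xor(!m$flipped, f),
                      mols, members$flip)
  members$tel <- vapply(mols, function(m) isTRUE(m$telomere_label), TRUE)
  members$tel_right <- as.logical(tel_right)
  structure(list(
    map = label_map(id, len, lab[!dup]),
    support = supp[!dup],
    n_molecules = nrow(members),
    coverage = sum(members$end - members$start) / len,
    members = members, mols = mols,
    conf_left = FALSE, conf_right = FALSE), class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %s: %d labels over %.0f bp, %d molecules, %.1fx\n",
              x$map$id, length(x$map$positions), x$map$length_bp,
              x$n_molecules, x$coverage))
  invisible(x)
}

#' Layout components and derive consensus maps
#'
#' Per weakly-connected component the highest-weight (sum of edge
#' scores) path defines the layout; remaining molecules are placed via
#' their best edge to an already-placed molecule. Consensus labels are
#' clusters of placed molecule labels (split at gaps wider than the
#' optical resolution) kept when their support reaches
#' `support_fraction` of the local molecule depth; positions are
#' cluster medians. Components with fewer than 3 molecules are
#' reported as failed to assemble.
#'
#' @param graph An `overlap_graph`.
#' @param params [pipeline_params()].
#' @return List with `contigs` (list of `consensus_map`) and `failed`
#'   (list of molecule index vectors).
#' @export
layout_and_consensus <- function(graph, params = pipeline_params()) {
  contigs <- list(); failed <- list()
  ed <- graph$edges
  for (cid in sort(unique(graph$components))) {
    vs <- which(graph$components == cid)
    if (length(vs) < 3) { failed[[length(failed) + 1L]] <- vs; next }
    sub <- ed[ed$from %in% vs & ed$to %in% vs, , drop = FALSE]
    # highest-weight path
    g <- igraph::graph_from_data_frame(
      sub[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = vs))
    topo <- as.integer(names(igraph::topo_sort(g)))
    best <- stats::setNames(rep(0, length(vs)), vs)
    pred <- stats::setNames(rep(NA_integer_, length(vs)), vs)
    for (v in topo) {
      ks <- which(sub$to == v)
      for (k in ks) {
        cand <- best[as.character(sub$from[k])] + sub$score[k]
        if (cand > best[as.character(v)]) {
          best[as.character(v)] <- cand
          pred[as.character(v)] <- sub$from[k]
        }
      }
    }
    v <- as.integer(names(best)[which.max(best)])
    path <- v
    while (!is.na(pred[as.character(v)])) {
      v <- pred[as.character(v)]
      path <- c(v, path)
    }
    pos <- stats::setNames(rep(NA_real_, length(vs)), vs)
    parent <- stats::setNames(rep(NA_integer_, length(vs)), vs)
    placed_order <- path
    pos[as.character(path[1])] <- 0
    for (k in seq_along(path)[-1]) {
      e <- sub[sub$from == path[k - 1] & sub$to == path[k], , drop = FALSE]
      pos[as.character(path[k])] <- pos[as.character(path[k - 1])] +
        e$offset[which.max(e$score)]
      parent[as.character(path[k])] <- path[k - 1]
    }
    # place the rest by best edge to a placed molecule
    repeat {
      unplaced <- vs[is.na(pos[as.character(vs)])]
      if (!length(unplaced)) break
      cand <- sub[xor(sub$from %in% unplaced, sub$to %in% unplaced), , drop = FALSE]
      cand <- cand[(!is.na(pos[as.character(cand$from)])) |
                   (!is.na(pos[as.character(cand$to)])), , drop = FALSE]
      if (!nrow(cand)) {  # disconnected leftovers (shouldn't happen)
        failed[[length(failed) + 1L]] <- unplaced
        vs <- setdiff(vs, unplaced)
        break
      }
      e <- cand[which.max(cand$score), , drop = FALSE]
      if (is.na(pos[as.character(e$to)])) {
        pos[as.character(e$to)] <- pos[as.character(e$from)] + e$offset
        parent[as.character(e$to)] <- e$from
        placed_order <- c(placed_order, e$to)
      } else {
        pos[as.character(e$from)] <- pos[as.character(e$to)] - e$offset
        parent[as.character(e$from)] <- e$to
        placed_order <- c(placed_order, e$from)
      }
    }
    if (length(vs) < 3) next
    # progressive consensus: walk molecules left to right and project
    # each through its alignment to the running consensus of the pool
    # so far (clusters seen by at least two molecules), so
    # per-interval sizing stretch does not accumulate into the pool
    span <- matrix(NA_real_, graph$n, 2)
    pool <- list()
    npooled <- 0L
    ordv <- placed_order[order(pos[as.character(placed_order)])]
    for (v in ordv) {
      m <- graph$molecules[[v]]
      om <- oriented_map(m$map, graph$flips[v])
      done <- FALSE
      if (npooled >= 2L) {
        pp <- do.call(rbind, pool)
        cl <- pool_clusters(pp$pos, pp$mol, params$optical_resolution_bp)
        med <- cl$center[cl$support >= 2]
        # only the pool near the molecule's graph placement is a valid
        # target; distant chance matches must not relocate it
        W <- 30000
        rigid <- pos[as.character(v)]
        med <- med[med >= rigid - W & med <= rigid + om$length_bp + W]
        if (length(med) >= params$min_aligned_labels) {
          base <- min(med)
          tgt <- label_map("pool", max(med) - base + 2, med - base)
          a <- align_overlap(om, tgt, params,
                             min_aligned = max(6L, params$min_aligned_labels %/% 2L),
                             min_score = params$min_score / 2)
          if (!is.null(a) && a$orientation == "+") {
            pr <- project_molecule(om$positions, om$length_bp,
                                   a$pairs[, "qi"],
                                   med[a$pairs[, "ti"]])
            if (abs(pr$start - rigid) <= 20000) {
              pool[[length(pool) + 1L]] <- data.frame(pos = pr$labels, mol = v)
              span[v, ] <- c(pr$start, pr$end)
              done <- TRUE
            }
          }
        }
      }
      if (!done) {
        pool[[length(pool) + 1L]] <-
          data.frame(pos = om$positions + pos[as.character(v)], mol = v)
        span[v, ] <- c(pos[as.character(v)],
                       pos[as.character(v)] + om$length_bp)
      }
      npooled <- npooled + 1L
    }
    members <- data.frame(idx = vs,
                          id = vapply(graph$molecules[vs],
                                      function(m) m$map$id, ""),
                          offset = span[vs, 1],
                          flip = graph$flips[vs],
                          start = span[vs, 1], end = span[vs, 2])
    cc <- consensus_from_pool(do.call(rbind, pool), members, params,
                              sprintf("contig%d", length(contigs) + 1L))
    mols <- graph$molecules[vs]
    tel_right <- mapply(function(m, f) xor(!m$flipped, f), mols,
                        cc$members$flip)
    cc$members$tel <- vapply(mols, function(m) isTRUE(m$telomere_label), TRUE)
    cc$members$tel_right <- as.logical(tel_right)
    cons <- structure(list(
      map = cc$map, support = cc$support,
      n_molecules = nrow(cc$members),
      coverage = sum(cc$members$end - cc$members$start) / cc$map$length_bp,
      members = cc$members, mols = mols,
      conf_left = FALSE, conf_right = FALSE), class = "consensus_map")
    contigs[[length(contigs) + 1L]] <- cons
  }
  list(contigs = contigs, failed = failed)
}

## end-evidence bookkeeping: telomere-labelled molecule ends and end
## pileups confirm a contig terminus
apply_end_evidence <- function(cons, params) {
  mem <- cons$members
  tol <- 2 * params$optical_resolution_bp
  L <- cons$map$length_bp
  tel <- mem$tel
  ends_tel <- ifelse(mem$tel_right, mem$end, mem$start)[tel]
  # a heterozygous assembly has telomere labels at two distinct
  # termini; capping at their median would truncate the longer allele,
  # so the cap only applies when one mode holds nearly all labelled ends
  unimodal <- FALSE
  if (length(ends_tel) >= params$telomere_confirm_k) {
    cl <- pool_clusters(ends_tel, seq_along(ends_tel),
                        2 * params$optical_resolution_bp)
    unimodal <- max(cl$support) >= 0.8 * length(ends_tel)
  }
  if (sum(tel) >= params$telomere_confirm_k && unimodal) {
    right <- sum(mem$tel_right[tel]) >= sum(tel) / 2
    cap <- stats::median(if (right) mem$end[tel] else mem$start[tel])
    if (right) {
      keep <- cons$map$positions <= cap
      cons$map <- label_map(cons$map$id, max(cap, max(c(0, cons$map$positions[keep])) + 1),
                            cons$map$positions[keep])
      cons$support <- cons$support[keep]
      cons$conf_right <- TRUE
    } else {
      keep <- cons$map$positions >= cap
      cons$map <- label_map(cons$map$id, L - floor(cap),
                            cons$map$positions[keep] - floor(cap))
      cons$support <- cons$support[keep]
      cons$members$offset <- cons$members$offset - floor(cap)
      cons$members$start <- cons$members$start - floor(cap)
      cons$members$end <- cons$members$end - floor(cap)
      cons$conf_left <- TRUE
    }
  }
  L <- cons$map$length_bp
  n_end_right <- sum(abs(cons$members$end - L) <= tol)
  n_end_left <- sum(abs(cons$members$start) <= tol)
  thr <- max(3, 0.15 * cons$n_molecules)
  if (n_end_right >= thr) cons$conf_right <- TRUE
  if (n_end_left >= thr) cons$conf_left <- TRUE
  cons
}

## project every label of a molecule into consensus coordinates:
## piecewise-linearly between matched pairs (absorbing sizing stretch),
## rigidly with the nearest matched pair beyond the aligned ends
project_molecule <- function(qpos, qlen, qi_or, cpos_matched) {
  x <- qpos[qi_or]; y <- cpos_matched
  proj <- qpos
  if (length(x) >= 2) {
    inside <- qpos >= x[1] & qpos <= x[length(x)]
    proj[inside] <- stats::approx(x, y, xout = qpos[inside], ties = "ordered")$y
  }
  proj[qpos < x[1]] <- qpos[qpos < x[1]] + (y[1] - x[1])
  k <- length(x)
  proj[qpos > x[k]] <- qpos[qpos > x[k]] + (y[k] - x[k])
  list(labels = proj,
       start = 0 + (y[1] - x[1]),
       end = qlen + (y[k] - x[k]))
}

## peak clustering of a pooled label set: repeatedly take the densest
## +-w window as one cluster (false-positive labels scattered between
## sites must not chain adjacent site clouds together)
pool_clusters <- function(pos, mol, w) {
  o <- order(pos); pos <- pos[o]; mol <- mol[o]
  n <- length(pos)
  if (!n) return(data.frame(center = numeric(0), support = integer(0)))
  active <- rep(TRUE, n)
  centers <- numeric(0); supports <- integer(0)
  while (any(active)) {
    ia <- which(active)
    ap <- pos[ia]
    lo <- findInterval(ap - w, ap)
    hi <- findInterval(ap + w, ap)
    cnt <- hi - lo
    if (max(cnt) <= 1L) {
      centers <- c(centers, ap)
      supports <- c(supports, rep(1L, length(ap)))
      break
    }
    i <- which.max(cnt)
    sel <- which(ap >= ap[i] - w & ap <= ap[i] + w)
    centers <- c(centers, stats::median(ap[sel]))
    supports <- c(supports, length(unique(mol[ia[sel]])))
    active[ia[sel]] <- FALSE
  }
  o <- order(centers)
  data.frame(center = centers[o], support = supports[o])
}

consensus_from_pool <- function(pool, mem, params, id) {
  shift <- min(mem$start)
  mem$start <- mem$start - shift
  mem$end <- mem$end - shift
  mem$offset <- mem$start
  pool$pos <- pool$pos - shift
  lab <- numeric(0); supp <- integer(0)
  if (nrow(pool)) {
    cl <- pool_clusters(pool$pos, pool$mol, params$optical_resolution_bp)
    for (k in seq_len(nrow(cl))) {
      depth <- sum(mem$start <= cl$center[k] & mem$end >= cl$center[k])
      thr <- max(ceiling(params$support_fraction * depth), min(2L, depth))
      if (cl$support[k] >= thr) {
        lab <- c(lab, round(cl$center[k])); supp <- c(supp, cl$support[k])
      }
    }
  }
  len <- max(mem$end)
  keep <- lab >= 0 & lab < len
  lab <- lab[keep]; supp <- supp[keep]
  o <- order(lab); lab <- lab[o]; supp <- supp[o]
  dup <- duplicated(lab)
  list(map = label_map(id, len, lab[!dup]), support = supp[!dup],
       members = mem)
}

#' Refine a consensus map and extend its ends
#'
#' Every member molecule is re-fit-aligned to the consensus and its
#' labels are projected into consensus coordinates piecewise-linearly
#' between matched label pairs (so per-interval sizing stretch does
#' not blur label clusters); label positions are recomputed as cluster
#' medians of the projections; labels hanging beyond either end with
#' sufficient support are appended. Iterated to a fixed point (no
#' label moves by more than 100 bp, none added or removed) or at most
#' `max_rounds` rounds. If enough members carry telomere end labels,
#' the consensus is capped at their common endpoint and never extends
#' beyond it.
#'
#' @param cons A `consensus_map`.
#' @param params [pipeline_params()].
#' @param max_rounds Maximum refinement rounds.
#' @return The refined `consensus_map`.
#' @export
refine_and_extend <- function(cons, params = pipeline_params(),
                              max_rounds = 5) {
  for (round in seq_len(max_rounds)) {
    old_pos <- cons$map$positions
    mem <- cons$members
    pool <- list()
    for (r in seq_len(nrow(mem))) {
      mol <- cons$mols[[r]]
      a <- align_overlap(mol$map, cons$map, params,
                         min_aligned = max(5L, params$min_aligned_labels %/% 2L),
                         min_score = params$min_score / 2)
      rigid_pool <- function() {
        qpos <- oriented_map(mol$map, mem$flip[r])$positions
        pool[[r]] <<- data.frame(pos = qpos + mem$offset[r], mol = r)
        mem$start[r] <<- mem$offset[r]
        mem$end[r] <<- mem$offset[r] + mol$map$length_bp
      }
      if (is.null(a)) { rigid_pool(); next }
      flip <- a$orientation == "-"
      qpos <- oriented_map(mol$map, flip)$positions
      qi_or <- if (flip) length(qpos) + 1L - a$pairs[, "qi"] else
        a$pairs[, "qi"]
      o <- order(qi_or)
      pr <- project_molecule(qpos, mol$map$length_bp, qi_or[o],
                             cons$map$positions[a$pairs[o, "ti"]])
      # a refit may not relocate the molecule far from its placement
      if (abs(pr$start - mem$offset[r]) > 20000 || flip != mem$flip[r]) {
        rigid_pool(); next
      }
      pool[[r]] <- data.frame(pos = pr$labels, mol = r)
      mem$start[r] <- pr$start
      mem$end[r] <- pr$end
      mem$offset[r] <- pr$start
    }
    pool <- do.call(rbind, pool)
    cc <- consensus_from_pool(pool, mem, params, cons$map$id)
    new <- cons
    new$map <- cc$map
    new$support <- cc$support
    new$members <- cc$members
    new$n_molecules <- nrow(cc$members)
    new$coverage <- sum(cc$members$end - cc$members$start) / cc$map$length_bp
    new <- apply_end_evidence(new, params)
    np <- new$map$positions; op <- old_pos
    converged <- length(np) == length(op) && length(op) > 0 &&
      max(abs((np - np[1]) - (op - op[1]))) <= 100
    cons <- new
    if (converged) break
  }
  cons
}

#' Split a consensus at an internal molecule-end pileup
#'
#' In a diploid genome an allele whose telomere lies centromeric of its
#' homologue's truncates all of its molecules at the same coordinate,
#' producing an excess of molecule ends strictly inside the joint
#' consensus while molecules of the other allele span through. When
#' such a pileup is found (and is not explained by a breakage site,
#' which piles up molecule starts too), the consensus is split into
#' the shorter allele (members ending at the pileup, truncated there)
#' and the longer one (members spanning past it, plus shared members
#' ending before it).
#'
#' @param cons A refined `consensus_map`.
#' @param params [pipeline_params()].
#' @return List of one (no split) or two `consensus_map`s.
#' @export
split_end_haplotypes <- function(cons, params = pipeline_params()) {
  mirror_consensus <- function(x) {
    L <- x$map$length_bp
    mem <- x$members
    news <- L - mem$end; newe <- L - mem$start
    mem$start <- news; mem$end <- newe; mem$offset <- news
    mem$flip <- !mem$flip
    mem$tel_right <- !mem$tel_right
    structure(list(map = reverse_map(x$map), support = rev(x$support),
                   n_molecules = x$n_molecules, coverage = x$coverage,
                   members = mem, mols = x$mols,
                   conf_left = x$conf_right, conf_right = x$conf_left),
              class = "consensus_map")
  }
  detect <- function(mem, L) {
    tol <- 2 * params$optical_resolution_bp
    cand_best <- NULL; best_n <- 0
    for (X in unique(round(mem$end))) {
      if (X < 50000 || X > L - params$gap_resolution_bp) next
      n_end <- sum(abs(mem$end - X) <= tol)
      n_span <- sum(mem$start < X - tol & mem$end > X + tol)
      n_start <- sum(abs(mem$start - X) <= tol)
      depth <- sum(mem$start <= X & mem$end >= X)
      if (n_span >= 5 && n_start < 3 &&
          n_end >= max(10, ceiling(0.35 * depth)) && n_end > best_n) {
        best_n <- n_end; cand_best <- X
      }
    }
    list(X = cand_best, n = best_n)
  }
  L <- cons$map$length_bp
  right <- detect(cons$members, L)
  left <- detect(mirror_consensus(cons)$members, L)
  if (is.null(right$X) && is.null(left$X)) return(list(cons))
  mirrored <- !is.null(left$X) && (is.null(right$X) || left$n > right$n)
  if (mirrored) cons <- mirror_consensus(cons)
  X <- if (mirrored) left$X else right$X
  mem <- cons$members
  tol <- 2 * params$optical_resolution_bp
  short_rows <- which(mem$end <= X + tol)
  long_rows <- which(mem$end > X + tol | mem$end < X - tol)
  mk <- function(rows, suffix) {
    m <- mem[rows, c("idx", "id", "offset", "flip")]
    consensus_from_placements(m, cons$mols[rows], params,
                              id = paste0(cons$map$id, suffix))
  }
  short <- mk(short_rows, "a")
  # truncate the short allele at the pileup (re-expressed in its own
  # frame: consensus_from_placements shifted the minimum offset to 0)
  Xs <- X - min(mem$offset[short_rows])
  keep <- short$map$positions <= Xs + tol
  newlen <- max(Xs, if (any(keep)) max(short$map$positions[keep]) + 1 else Xs)
  short$map <- label_map(short$map$id, newlen, short$map$positions[keep])
  short$support <- short$support[keep]
  short$conf_right <- TRUE
  long <- mk(long_rows, "b")
  out <- list(refine_and_extend(short, params),
              refine_and_extend(long, params))
  if (mirrored) out <- lapply(out, mirror_consensus)
  out
}

#' Merge overlapping consensus maps
#'
#' Pairs whose dovetail alignment exceeds the acceptance thresholds,
#' agrees over at least `merge_span_fraction` of the labels inside the
#' implied shared span on both maps, and does not extend past a
#' confirmed terminus of either map are merged (union of member
#' placements, re-consensus, one refinement round). Idempotent.
#'
#' @param contigs List of `consensus_map`s.
#' @param params [pipeline_params()].
#' @return List of merged `consensus_map`s.
#' @export
merge_consensus <- function(contigs, params = pipeline_params()) {
  repeat {
    merged <- FALSE
    nc <- length(contigs)
    if (nc < 2) break
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        ci <- contigs[[i]]; cj <- contigs[[j]]
        a <- align_overlap(cj$map, ci$map, params)
        if (is.null(a)) next
        off <- a$offset
        Li <- ci$map$length_bp; Lj <- cj$map$length_bp
        lo <- max(0, off); hi <- min(Li, off + Lj)
        if (hi <= lo) next
        jpos <- oriented_map(cj$map, a$orientation == "-")$positions + off
        ni <- sum(ci$map$positions >= lo & ci$map$positions <= hi)
        nj <- sum(jpos >= lo & jpos <= hi)
        if (ni == 0 || nj == 0) next
        if (a$n_pairs / ni < params$merge_span_fraction ||
            a$n_pairs / nj < params$merge_span_fraction) next
        # confirmed termini must not be overhung
        gr <- params$gap_resolution_bp
        jl <- if (a$orientation == "+") cj$conf_left else cj$conf_right
        jr <- if (a$orientation == "+") cj$conf_right else cj$conf_left
        if (ci$conf_right && off + Lj > Li + gr) next
        if (ci$conf_left && off < -gr) next
        if (jr && Li > off + Lj + gr) next
        if (jl && off > gr) next
        # merge j into i's frame
        memj <- cj$members
        if (a$orientation == "-") {
          new_off <- off + (Lj - memj$end)
          memj$offset <- new_off
          memj$flip <- !memj$flip
        } else {
          memj$offset <- off + memj$offset
        }
        mem <- rbind(ci$members[, c("idx", "id", "offset", "flip")],
                     memj[, c("idx", "id", "offset", "flip")])
        mols <- c(ci$mols, cj$mols)
        dup <- duplicated(mem$id)
        mem <- mem[!dup, , drop = FALSE]
        mols <- mols[!dup]
        new <- consensus_from_placements(mem, mols, params, id = ci$map$id)
        new$conf_left <- ci$conf_left || (if (a$orientation == "+") cj$conf_left else cj$conf_right)
        new$conf_right <- ci$conf_right || jr
        new <- refine_and_extend(new, params, max_rounds = 2)
        contigs[[i]] <- new
        contigs[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  contigs
}

#' Assemble molecules end-to-end
#'
#' Convenience wrapper chaining [build_overlap_graph()],
#' [layout_and_consensus()], [refine_and_extend()],
#' [split_end_haplotypes()] and [merge_consensus()].
#'
#' @param molecules List of `sim_molecule`s.
#' @param params [pipeline_params()].
#' @return List with `contigs` and `failed` (as molecule index sets).
#' @export
assemble_molecules <- function(molecules, params = pipeline_params()) {
  graph <- build_overlap_graph(molecules, params)
  lay <- layout_and_consensus(graph, params)
  contigs <- list()
  for (cons in lay$contigs) {
    cons <- refine_and_extend(cons, params)
    for (part in split_end_haplotypes(cons, params))
      contigs[[length(contigs) + 1L]] <- part
  }
  contigs <- merge_consensus(contigs, params)
  for (k in seq_along(contigs))
    contigs[[k]]$map$id <- sprintf("contig%d", k)
  list(contigs = contigs, failed = lay$failed)
}
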