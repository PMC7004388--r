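#' Block, haplotype and population specifications
#'
#' A block spec names a paralogy block and fixes the nick pattern that
#' identifies it: a vector of inter-label distances. A haplotype spec
#' composes a subtelomeric haplotype from a 1-copy anchor followed by
#' an ordered series of oriented blocks; the reference version of a
#' haplotype may additionally carry a terminal N-gap pad. A population
#' spec fixes super-population sizes and per-arm haplotype frequencies.
#'
#' @param name Block / haplotype name.
#' @param label_spacings Positive inter-label distances, bp.
#' @param length_bp Total block length; defaults to the spacing sum
#'   plus a short unlabelled margin.
#' @return `block_spec`, `haplotype_spec`, `population_spec` objects.
#' @export
block_spec <- function(name, label_spacings, length_bp = NULL) {
  label_spacings <- as.numeric(label_spacings)
  stopifnot(all(label_spacings > 0))
  if (is.null(length_bp)) length_bp <- sum(label_spacings) + 2000
  stopifnot(sum(label_spacings) < length_bp)
  structure(list(name = name, label_spacings = label_spacings,
                 length_bp = length_bp), class = "block_spec")
}

#' @rdname block_spec
#' @param arm Arm name the haplotype belongs to.
#' @param block_order List of `c(block_name, orientation)` pairs, or
#'   character vector of names optionally suffixed with `"-"` for
#'   reversed blocks (e.g. `"B3-"`).
#' @param onecopy_bp Length of the 1-copy anchor region, bp (>= 1e5 so
#'   molecules anchor meaningfully).
#' @param terminal_gap_bp Terminal N-gap appended in the reference
#'   version only, bp.
#' @param extension_bp Signed offset of the true telomere relative to
#'   the reference sequenced end (truth annotation).
#' @param terminal_pad_bp Unlabelled DNA between the last label and the
#'   telomere, bp.
#' @param anchor_seed Seed fixing the anchor's label pattern; defaults
#'   to a hash of `arm` so each arm's 1-copy pattern is distinct but
#'   stable.
#' @export
haplotype_spec <- function(name, arm, block_order = character(0),
                           onecopy_bp = 300000, terminal_gap_bp = 0,
                           extension_bp = 0, terminal_pad_bp = 8000,
                           anchor_seed = NULL) {
  stopifnot(onecopy_bp >= 100000)
  if (is.null(anchor_seed))
    anchor_seed <- sum(utf8ToInt(arm) * seq_len(nchar(arm))) * 131L
  structure(list(name = name, arm = arm, block_order = block_order,
                 onecopy_bp = onecopy_bp, terminal_gap_bp = terminal_gap_bp,
                 extension_bp = extension_bp,
                 terminal_pad_bp = terminal_pad_bp,
                 anchor_seed = as.integer(anchor_seed %% 2147483647)),
            class = "haplotype_spec")
}

#' @rdname block_spec
#' @param sizes Named super-population sizes; defaults emulate a
#'   154-genome cohort (42 AFR, 30 AMR, 30 EAS, 24 EUR, 28 SAS).
#' @param freqs Named list, one entry per arm: a matrix with one row
#'   per super-population and one column per haplotype name, rows
#'   summing to 1.
#' @export
population_spec <- function(sizes = c(AFR = 42, AMR = 30, EAS = 30,
                                      EUR = 24, SAS = 28),
                            freqs = list()) {
  stopifnot(all(sizes > 0), !is.null(names(sizes)))
  for (arm in names(freqs)) {
    f <- freqs[[arm]]
    stopifnot(is.matrix(f), all(names(sizes) %in% rownames(f)))
    if (any(abs(rowSums(f) - 1) > 1e-9))
      stop(sprintf("haplotype frequencies for arm %s must sum to 1", arm))
  }
  structure(list(sizes = sizes, freqs = freqs), class = "population_spec")
}

#' Default paralogy-block library
#'
#' Eight named blocks with distinct seeded spacing vectors (5--9
#' labels, inter-label spacings 3--12 kb), collision-checked so no
#' block's pattern fit-aligns to another's above the detection
#' threshold.
#'
#' @param seed Seed fixing the library (default 20).
#' @return Named list of [block_spec()] objects `B1`..`B8`.
#' @export
default_block_library <- function(seed = 20) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  libr <- list()
  nlab <- c(6, 5, 9, 7, 8, 5, 7, 6)
  params <- pipeline_params()
  collides <- function(sp, others) {
    # a candidate pattern may not fit-align into any accepted block
    # (either way round) at the detection thresholds
    for (ot in others) {
      for (pair in list(list(sp, ot), list(ot, sp))) {
        pat <- label_map("p", sum(pair[[1]]) + 1, cumsum(c(0, pair[[1]])))
        tgt <- label_map("t", sum(pair[[2]]) + 1, cumsum(c(0, pair[[2]])))
        npat <- length(pat$positions)
        a <- align_fit(pat, tgt, params,
                       min_aligned = ceiling(params$block_match_fraction * npat),
                       min_score = params$block_min_mean_score *
                         ceiling(params$block_match_fraction * npat))
        if (!is.null(a) && a$n_pairs / npat >= params$block_match_fraction &&
            a$score / a$n_pairs >= params$block_min_mean_score)
          return(TRUE)
      }
    }
    FALSE
  }
  for (k in 1:8) {
    for (attempt in 0:49) {
      set.seed(seed * 1000 + k * 37 + attempt)
      sp <- round(stats::runif(nlab[k] - 1, 3000, 12000))
      if (!collides(sp, lapply(libr, `[[`, "label_spacings"))) break
    }
    libr[[paste0("B", k)]] <- block_spec(paste0("B", k), sp)
  }
  libr
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## TRUE when any library block pattern fit-aligns into the candidate
## anchor label pattern at block-detection acceptance thresholds
anchor_collides <- function(pos, len, library,
                            params = pipeline_params()) {
  anchor <- label_map("anchor", len, round(pos))
  for (b in library) {
    if (length(b$label_spacings) < 2) next
    pat <- label_map(b$name, sum(b$label_spacings) + 1,
                     cumsum(c(0, b$label_spacings)))
    npat <- length(pat$positions)
    if (npat < 3) next
    a <- align_fit(pat, anchor, params,
                   min_aligned = ceiling(params$block_match_fraction * npat),
                   min_score = params$block_min_mean_score *
                     ceiling(params$block_match_fraction * npat))
    if (!is.null(a) && a$n_pairs / npat >= params$block_match_fraction &&
        a$score / a$n_pairs >= params$block_min_mean_score)
      return(TRUE)
  }
  FALSE
}

parse_block_order <- function(block_order) {
  if (!length(block_order)) return(list())
  if (is.list(block_order))
    return(lapply(block_order, function(b)
      list(name = b[[1]], orient = if (length(b) > 1) b[[2]] else "+")))
  lapply(block_order, function(b) {
    if (grepl("-$", b)) list(name = sub("-$", "", b), orient = "-")
    else list(name = b, orient = "+")
  })
}

#' Compose a haplotype label map from its specification
#'
#' Concatenates the 1-copy anchor pattern (seeded random spacings,
#' distinct from all block patterns) and the ordered, oriented blocks,
#' finishing with an unlabelled terminal pad up to the telomere.
#' Returns the map plus a truth annotation recording block intervals
#' and the true telomere coordinate (= map length).
#'
#' @param spec [haplotype_spec()].
#' @param library Named list of [block_spec()]s.
#' @param junction_bp Unlabelled spacing inserted at block junctions.
#' @return A [label_map()] with attributes `truth` (data.frame of block
#'   intervals) and `spec`.
#' @export
compose_haplotype <- function(spec, library = default_block_library(),
                              junction_bp = 6000) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  # anchor: mean spacing ~8 kb over onecopy_bp; the 1-copy pattern must
  # not contain a chance copy of any library block pattern, or block
  # detection would see phantom blocks in single-copy DNA
  n_anchor <- max(3L, floor(spec$onecopy_bp / 8000) - 1L)
  for (attempt in 0:24) {
    set.seed(spec$anchor_seed + attempt)
    asp <- stats::runif(n_anchor - 1L, 4000, 12000)
    asp <- asp * (spec$onecopy_bp - 4000) / sum(asp)
    pos <- 2000 + cumsum(c(0, asp))
    if (!anchor_collides(pos, spec$onecopy_bp, library)) break
  }
  cursor <- spec$onecopy_bp
  truth <- list()
  for (b in parse_block_order(spec$block_order)) {
    if (is.null(library[[b$name]])) stop("unknown block: ", b$name)
    bs <- library[[b$name]]
    sp <- bs$label_spacings
    if (b$orient == "-") sp <- rev(sp)
    start <- cursor + junction_bp
    bpos <- start + cumsum(c(0, sp))
    pos <- c(pos, bpos)
    cursor <- start + sum(sp)
    truth[[length(truth) + 1L]] <-
      data.frame(block = bs$name, orient = b$orient,
                 start = start, end = cursor)
  }
  len <- cursor + spec$terminal_pad_bp
  map <- label_map(spec$name, len, round(pos))
  attr(map, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(block = character(0), orient = character(0),
               start = numeric(0), end = numeric(0))
  attr(map, "spec") <- spec
  map
}

#' Build a reference arm from a reference haplotype specification
#'
#' The reference version of the arm is the composed haplotype followed
#' by `terminal_gap_bp` of N (unlabelled) padding up to the annotated
#' chromosome end.
#'
#' @param spec [haplotype_spec()] of the reference haplotype.
#' @param library Block library.
#' @return A [reference_arm()]; the underlying map keeps its `truth`
#'   attribute.
#' @export
build_reference_arm <- function(spec, library = default_block_library()) {
  m <- compose_haplotype(spec, library)
  seq_end <- m$length_bp
  g <- spec$terminal_gap_bp
  padded <- label_map(spec$arm, seq_end + g, m$positions)
  attr(padded, "truth") <- attr(m, "truth")
  reference_arm(spec$arm, padded,
                gaps = if (g > 0) gap_intervals(seq_end, seq_end + g)
                       else gap_intervals(),
                window_bp = seq_end + g,
                tel_end_bp = seq_end, arm_end_bp = seq_end + g,
                onecopy_interval = c(0, spec$onecopy_bp))
}

#' Sample a diploid population
#'
#' Each genome draws, per arm, two independent haplotypes from its
#' super-population's frequency vector. Deterministic under `seed`.
#'
#' @param pop [population_spec()].
#' @param seed Integer seed.
#' @return data.frame with one row per genome x arm: `genome`,
#'   `superpop`, `arm`, `hap1`, `hap2`.
#' @export
sample_population <- function(pop, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  superpop <- rep(names(pop$sizes), pop$sizes)
  genomes <- sprintf("G%03d", seq_along(superpop))
  rows <- list()
  for (arm in names(pop$freqs)) {
    f <- pop$freqs[[arm]]
    haps <- colnames(f)
    for (i in seq_along(genomes)) {
      pr <- f[superpop[i], ]
      draw <- sample(haps, 2L, replace = TRUE, prob = pr)
      rows[[length(rows) + 1L]] <-
        data.frame(genome = genomes[i], superpop = superpop[i], arm = arm,
                   hap1 = draw[1], hap2 = draw[2])
    }
  }
  if (!length(rows))
    return(data.frame(genome = genomes, superpop = superpop))
  do.call(rbind, rows)
}

## ---- molecule simulation ----------------------------------------------

new_molecule <- function(map, genome = NA, arm = NA, hap = NA,
                         start = NA, tel = FALSE, inp = FALSE,
                         flipped = FALSE) {
  structure(list(map = map, genome = genome, arm = arm, hap = hap,
                 start = start, telomere_label = tel,
                 broken_at_inp = inp, flipped = flipped),
            class = "sim_molecule")
}

merge_close_labels <- function(pos, res) {
  if (length(pos) < 2) return(pos)
  pos <- sort(pos)
  out <- numeric(0)
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur < res) cur <- (cur + p) / 2
    else { out <- c(out, cur); cur <- p }
  }
  c(out, cur)
}

#' Simulate error-bearing single-molecule label maps
#'
#' Molecules are drawn with a shifted-exponential length model (minimum
#' `min_molecule_bp`, mean `mean_molecule_bp`), truncated at the map
#' ends, until mean coverage reaches `coverage`. Each true label is
#' dropped with probability `fn_rate`; spurious labels arrive as a
#' homogeneous Poisson process whose rate makes the expected
#' false-positive fraction of observed labels equal `fp_rate`;
#' inter-label intervals get multiplicative Gaussian sizing noise
#' (`sizing_cv`) and labels additive jitter (`jitter_bp`); labels
#' closer than `optical_resolution_bp` merge to their midpoint.
#' Molecules spanning an inverted-nick-pair site break there with
#' probability `p_break` (fragments are kept whatever their length).
#' Molecules whose distal end reaches the true telomere carry
#' `telomere_label = TRUE` when end labelling is enabled.
#'
#' @param genome_map Haplotype [label_map()] (nonempty).
#' @param params [pipeline_params()].
#' @param inp_sites Numeric positions of INP sites on the map.
#' @param seed Integer seed.
#' @param coverage Target mean coverage (default
#'   `params$min_coverage`).
#' @param telomere_labeling Logical: simulate telomere end labels.
#' @param orient_random Logical: present each molecule in a random
#'   orientation, as instrument output would be.
#' @param genome,arm,hap Truth annotations carried on each molecule.
#' @return List of `sim_molecule` objects.
#' @export
simulate_molecules <- function(genome_map, params = pipeline_params(),
                               inp_sites = numeric(0), seed = 1,
                               coverage = params$min_coverage,
                               telomere_labeling = TRUE,
                               orient_random = TRUE,
                               genome = NA, arm = NA, hap = NA) {
  L <- genome_map$length_bp
  if (!length(genome_map$positions)) stop("genome_map has no labels")
  if (L < params$min_molecule_bp)
    stop("map shorter than the minimum molecule length; coverage unreachable")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  truth_pos <- genome_map$positions
  density <- length(truth_pos) / L
  lambda_fp <- if (params$fp_rate > 0)
    params$fp_rate / (1 - params$fp_rate) * (1 - params$fn_rate) * density
  else 0
  mols <- list()
  total <- 0
  while (total < coverage * L) {
    len <- params$min_molecule_bp +
      stats::rexp(1, 1 / max(1, params$mean_molecule_bp - params$min_molecule_bp))
    start <- stats::runif(1, 0, max(1, L - params$min_molecule_bp))
    end <- min(start + len, L)
    if (end - start < params$min_molecule_bp) next
    # INP breakage decides fragment intervals first
    cuts <- numeric(0)
    for (s in inp_sites)
      if (s > start && s < end && stats::runif(1) < params$p_break)
        cuts <- c(cuts, s)
    bounds <- sort(unique(c(start, cuts, end)))
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k]; b <- bounds[k + 1L]
      frag_len <- b - a
      tl <- telomere_labeling && (b >= L)
      p <- truth_pos[truth_pos >= a & truth_pos < b] - a
      keep <- stats::runif(length(p)) >= params$fn_rate
      p <- p[keep]
      if (length(p) > 1 && params$sizing_cv > 0) {
        d <- diff(p) * stats::rnorm(length(p) - 1, 1, params$sizing_cv)
        p <- p[1] + cumsum(c(0, d))
      }
      if (length(p) && params$jitter_bp > 0)
        p <- p + stats::rnorm(length(p), 0, params$jitter_bp)
      nfp <- if (lambda_fp > 0) stats::rpois(1, lambda_fp * frag_len) else 0
      if (nfp > 0) p <- c(p, stats::runif(nfp, 0, frag_len))
      p <- pmin(pmax(p, 0), frag_len - 1)
      p <- merge_close_labels(p, params$optical_resolution_bp)
      p <- sort(unique(round(p)))
      flip <- orient_random && stats::runif(1) < 0.5
      m <- label_map(sprintf("mol%05d", length(mols) + 1L), round(frag_len), p)
      if (flip) m <- reverse_map(m)
      mols[[length(mols) + 1L]] <-
        new_molecule(m, genome, arm, hap, start = a,
                     tel = tl, inp = length(cuts) > 0, flipped = flip)
    }
    total <- total + (end - start)
  }
  mols
}

## ---- simplified BNX dialect -------------------------------------------

#' Read / write simulated molecules in the simplified BNX dialect
#'
#' `#`-prefixed header; per molecule a `0 <id> <length_bp>` line, a
#' `1 <pos> ...` label line, and a `# truth ...` comment carrying the
#' simulation truth so evaluation never needs side files.
#'
#' @param molecules List of `sim_molecule` objects.
#' @param path File path.
#' @return `read_bnx` returns the list of molecules; `write_bnx`
#'   returns `path` invisibly.
#' @export
write_bnx <- function(molecules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# simplified BNX (single channel)", con)
  for (m in molecules) {
    writeLines(sprintf("0\t%s\t%.0f", m$map$id, m$map$length_bp), con)
    writeLines(paste(c("1", sprintf("%.0f", m$map$positions)),
                     collapse = "\t"), con)
    writeLines(sprintf(
      "# truth genome=%s arm=%s hap=%s start=%.0f tel=%d inp=%d flip=%d",
      m$genome, m$arm, m$hap, m$start,
      as.integer(m$telomere_label), as.integer(m$broken_at_inp),
      as.integer(m$flipped)), con)
  }
  invisible(path)
}

#' @rdname write_bnx
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  mols <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^0\t", ln)) {
      f <- strsplit(ln, "\t")[[1]]
      if (i + 1L > length(lines) || !grepl("^1(\t|$)", lines[i + 1L]))
        stop(sprintf("malformed BNX: molecule at line %d lacks a label line", i))
      lab <- strsplit(lines[i + 1L], "\t")[[1]][-1]
      pos <- if (length(lab)) as.numeric(lab) else numeric(0)
      if (anyNA(pos))
        stop(sprintf("malformed BNX label line at line %d", i + 1L))
      m <- new_molecule(label_map(f[2], as.numeric(f[3]), pos))
      if (i + 2L <= length(lines) && grepl("^# truth ", lines[i + 2L])) {
        kv <- strsplit(sub("^# truth ", "", lines[i + 2L]), " ")[[1]]
        kv <- strsplit(kv, "=")
        vals <- stats::setNames(vapply(kv, `[`, "", 2),
                                vapply(kv, `[`, "", 1))
        m$genome <- vals[["genome"]]; m$arm <- vals[["arm"]]
        m$hap <- vals[["hap"]]
        m$start <- as.numeric(vals[["start"]])
        m$telomere_label <- vals[["tel"]] == "1"
        m$broken_at_inp <- vals[["inp"]] == "1"
        m$flipped <- vals[["flip"]] == "1"
        i <- i + 1L
      }
      mols[[length(mols) + 1L]] <- m
      i <- i + 2L
    } else if (grepl("^#", ln) || !nzchar(ln)) {
      i <- i + 1L
    } else {
      stop(sprintf("malformed BNX record at line %d", i))
    }
  }
  mols
}
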