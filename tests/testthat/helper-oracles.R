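## Independent oracles used to freeze expected values: brute-force
## enumeration for the aligner, per-base / regex scans for sequence
## operations, textbook formulas for statistics.

## exhaustive search over all monotone chunk chains with bounded
## interior skips; same scoring rules as the spec'd chunk model, but
## enumerated rather than solved by dynamic programming
oracle_chain_score <- function(q, t, params, mode = c("fit", "overlap")) {
  mode <- match.arg(mode)
  m <- length(q); n <- length(t)
  if (m == 0 || n == 0) return(-Inf)
  reward <- params$match_reward
  fp <- params$fp_penalty; fn <- params$fn_penalty
  ms <- params$max_skip
  chunk <- function(dq, dr, nq, nr) {
    v <- params$sizing_cv^2 * dr^2 + 2 * params$jitter_bp^2
    reward - (dq - dr)^2 / (2 * v) - nq * fp - nr * fn
  }
  best <- -Inf
  recurse <- function(i, j, sc) {
    fin <- if (mode == "fit") sc - (m - i) * fp else sc
    if (fin > best) best <<- fin
    if (i < m && j < n) {
      for (i2 in seq.int(i + 1, min(m, i + 1 + ms))) {
        for (j2 in seq.int(j + 1, min(n, j + 1 + ms))) {
          recurse(i2, j2,
                  sc + chunk(q[i2] - q[i], t[j2] - t[j],
                             i2 - i - 1, j2 - j - 1))
        }
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      recurse(i, j, if (mode == "fit") reward - (i - 1) * fp else reward)
    }
  }
  best
}

## both orientations, like the aligner's wrappers
oracle_align_score <- function(query, target, params, mode) {
  s1 <- oracle_chain_score(query$positions, target$positions, params, mode)
  qr <- rev(query$length_bp - 1 - query$positions)
  s2 <- oracle_chain_score(qr, target$positions, params, mode)
  max(s1, s2)
}

## regex scan of both strands for motif occurrences (digestion oracle)
oracle_digest_positions <- function(seq, motif = "GCTCTTC") {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- function(pat) {
    r <- gregexpr(sprintf("(?=%s)", pat), seq, perl = TRUE)[[1]]
    if (r[1] == -1) integer(0) else as.integer(r) - 1L
  }
  fwd <- hits(motif)
  rev_ <- hits(revcomp(motif)) + nchar(motif) - 1L
  sort(unique(c(fwd, rev_)))
}

## per-base scan for N runs
oracle_n_runs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "N") {
      j <- i
      while (j < length(ch) && ch[j + 1L] == "N") j <- j + 1L
      out <- rbind(out, c(i - 1L, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

## brute-force pair scan for inverted nick pairs
oracle_inp <- function(pos, strands, dist) {
  hits <- NULL
  for (k in seq_len(length(pos) - 1L)) {
    if (strands[k] != strands[k + 1L] && pos[k + 1L] - pos[k] <= dist)
      hits <- rbind(hits, c((pos[k] + pos[k + 1L]) / 2, pos[k + 1L] - pos[k]))
  }
  hits
}

## textbook one-way ANOVA F statistic
oracle_anova_F <- function(y, g) {
  g <- as.factor(g)
  gm <- tapply(y, g, mean)
  nk <- tapply(y, g, length)
  ssb <- sum(nk * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

## random label map with resolvable spacings
rand_map <- function(n, seed, min_gap = 2000, max_gap = 20000, id = "r") {
  set.seed(seed)
  pos <- cumsum(round(runif(n, min_gap, max_gap)))
  label_map(id, max(pos) + 1000, pos)
}

## error-free molecules tiling a truth map
tile_molecules <- function(truth, n = 60, mol_len = 300000, flip_seed = NULL) {
  L <- truth$length_bp
  starts <- seq(0, L - mol_len, length.out = n)
  lapply(seq_along(starts), function(k) {
    s <- round(starts[k]); e <- min(s + mol_len, L)
    m <- slice_map(truth, s, e, sprintf("m%03d", k))
    fl <- FALSE
    if (!is.null(flip_seed)) {
      set.seed(flip_seed + k); fl <- runif(1) < 0.5
      if (fl) m <- reverse_map(m)
    }
    structure(list(map = m, genome = NA, arm = NA, hap = NA, start = s,
                   telomere_label = FALSE, broken_at_inp = FALSE,
                   flipped = fl), class = "sim_molecule")
  })
}

## cache shared across test files (expensive simulated assemblies)
.test_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache))
    assign(name, force(expr), envir = .test_cache)
  get(name, envir = .test_cache)
}
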