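#' Nicking-enzyme motif
#'
#' @param name Short enzyme name.
#' @param recognition Recognition sequence, unambiguous A/C/G/T only,
#'   at least 5 bases.
#' @param label_offset Offset in bp from motif start to the reported
#'   label position.
#' @return An object of class `nick_motif`.
#' @export
nick_motif <- function(name = "Nt.BspQI", recognition = "GCTCTTC",
                       label_offset = 0L) {
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) >= 5,
            grepl("^[ACGT]+$", recognition),
            label_offset >= 0)
  structure(list(name = name, recognition = recognition,
                 label_offset = as.integer(label_offset)),
            class = "nick_motif")
}

#' In silico nick digestion of a DNA sequence
#'
#' Scans both strands for the motif and reports one label per
#' occurrence: at `start + label_offset` for forward hits and
#' `end - 1 - label_offset` for reverse-strand hits (0-based). The
#' motif contains only A/C/G/T, so occurrences never overlap N runs.
#' When forward and reverse labels coincide a single label is kept with
#' strand `"+"`.
#'
#' @param sequence DNA string over A/C/G/T/N (or a
#'   [Biostrings::DNAString]).
#' @param motif A [nick_motif()].
#' @param id Identifier for the returned map.
#' @return A [label_map()] with strand annotation.
#' @export
in_silico_digest <- function(sequence, motif = nick_motif(), id = "map") {
  if (is.character(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) && !grepl("^[ACGTN]*$", sequence))
      stop("sequence must contain only A, C, G, T or N")
    sequence <- Biostrings::DNAString(if (nchar(sequence)) sequence else "")
  }
  L <- length(sequence)
  if (L == 0) return(label_map(id, 0))
  fwd <- Biostrings::matchPattern(motif$recognition, sequence)
  rcm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif$recognition)))
  rev <- Biostrings::matchPattern(rcm, sequence)
  fpos <- Biostrings::start(fwd) - 1L + motif$label_offset
  rpos <- Biostrings::end(rev) - 1L - motif$label_offset
  pos <- c(fpos, rpos)
  str <- c(rep("+", length(fpos)), rep("-", length(rpos)))
  keep <- pos >= 0 & pos < L
  pos <- pos[keep]; str <- str[keep]
  o <- order(pos, str)  # "+" sorts before "-"
  pos <- pos[o]; str <- str[o]
  dup <- duplicated(pos)
  label_map(id, L, pos[!dup], str[!dup])
}

#' Locate N-gap intervals in a sequence
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @return Maximal runs of N as sorted [gap_intervals()] (0-based
#'   half-open).
#' @export
find_gap_intervals <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) && !grepl("^[ACGTN]*$", sequence))
    stop("sequence must contain only A, C, G, T or N")
  if (!nchar(sequence)) return(gap_intervals())
  r <- rle(strsplit(sequence, "")[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gap_intervals(starts[r$values], ends[r$values])
}

#' Extract the distal subtelomere window of a chromosome arm
#'
#' Returns the distal `window_bp` of the arm re-coordinated so position
#' increases toward the telomere: q arms are shifted, p arms are
#' mirrored. `tel_end_bp` is set to the window end minus any terminal
#' N run, `arm_end_bp` to the window end.
#'
#' @param chrom_map [label_map()] covering the whole chromosome (or
#'   arm), coordinates increasing from pter.
#' @param gaps [gap_intervals()] in chromosome coordinates.
#' @param arm Arm name ending in `"p"` or `"q"`.
#' @param window_bp Window size, bp.
#' @param onecopy_interval Optional `c(start, end)` in the returned
#'   (telomere-distal-increasing) window coordinates.
#' @return A [reference_arm()].
#' @export
extract_subtelomere_window <- function(chrom_map, gaps = gap_intervals(),
                                       arm, window_bp = 500000,
                                       onecopy_interval = NULL) {
  side <- substring(arm, nchar(arm))
  stopifnot(side %in% c("p", "q"))
  L <- chrom_map$length_bp
  if (L < window_bp) {
    warning(sprintf("chromosome (%.0f bp) shorter than window; using full length", L))
    window_bp <- L
  }
  if (side == "q") {
    from <- L - window_bp
    wmap <- slice_map(chrom_map, from, L, id = arm)
    g <- gaps[gaps$end > from & gaps$start < L, , drop = FALSE]
    g <- gap_intervals(pmax(g$start - from, 0), pmin(g$end - from, window_bp))
  } else {
    wmap <- reverse_map(slice_map(chrom_map, 0, window_bp, id = arm))
    g <- gaps[gaps$start < window_bp, , drop = FALSE]
    s <- window_bp - pmin(g$end, window_bp)
    e <- window_bp - pmax(g$start, 0)
    g <- gap_intervals(s, e)
  }
  tel_end <- window_bp
  if (nrow(g) && g$end[nrow(g)] == window_bp) tel_end <- g$start[nrow(g)]
  if (is.null(onecopy_interval)) onecopy_interval <- c(0, tel_end)
  reference_arm(arm, wmap, g, window_bp = window_bp,
                tel_end_bp = tel_end, arm_end_bp = window_bp,
                onecopy_interval = onecopy_interval)
}

#' Digest a FASTA file into reference arms
#'
#' Convenience wrapper: reads a (multi-)FASTA, digests each record,
#' locates its N gaps, and extracts the distal window for the arm named
#' by the record (record names must end in `p` or `q`).
#'
#' @param fasta Path to a FASTA file.
#' @param motif A [nick_motif()].
#' @param window_bp Window size, bp.
#' @return A named list of [reference_arm()] objects.
#' @export
digest_fasta <- function(fasta, motif = nick_motif(), window_bp = 500000) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  arms <- lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    s <- seqs[[i]]
    extract_subtelomere_window(in_silico_digest(s, motif, id = nm),
                               find_gap_intervals(as.character(s)),
                               arm = nm, window_bp = window_bp)
  })
  names(arms) <- names(seqs)
  arms
}

## ---- simplified CMAP dialect ------------------------------------------

#' Read / write label maps in the simplified CMAP dialect
#'
#' Tab-separated, `#`-prefixed header lines, columns CMapId,
#' ContigLength, NumSites, SiteID, LabelChannel, Position; each map
#' carries one terminal pseudo-site with Position = ContigLength. Not
#' byte-compatible with vendor CMAP; extra columns are tolerated on
#' read.
#'
#' @param maps List of [label_map()] objects.
#' @param path File path.
#' @return `read_cmap` returns a named list of `label_map`s;
#'   `write_cmap` returns `path` invisibly.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# simplified CMAP (single channel)",
               "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition"),
             con)
  for (m in maps) {
    n <- length(m$positions)
    pos <- c(m$positions, m$length_bp)
    site <- seq_len(n + 1L)
    ch <- c(rep(m$channel, n), 0L)
    writeLines(sprintf("%s\t%.0f\t%d\t%d\t%d\t%.0f",
                       m$id, m$length_bp, n, site, ch, pos), con)
  }
  invisible(path)
}

#' @rdname write_cmap
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(body)) return(list())
  fields <- strsplit(lines[body], "\t")
  bad <- which(lengths(fields) < 6)
  if (length(bad))
    stop(sprintf("malformed CMAP record at line %d: expected >= 6 columns",
                 body[bad[1]]))
  d <- data.frame(id = vapply(fields, `[`, "", 1),
                  len = as.numeric(vapply(fields, `[`, "", 2)),
                  nsites = as.integer(vapply(fields, `[`, "", 3)),
                  site = as.integer(vapply(fields, `[`, "", 4)),
                  channel = as.integer(vapply(fields, `[`, "", 5)),
                  pos = as.numeric(vapply(fields, `[`, "", 6)),
                  line = body)
  if (anyNA(d$pos) || anyNA(d$len))
    stop(sprintf("malformed CMAP numeric field at line %d",
                 d$line[which(is.na(d$pos) | is.na(d$len))[1]]))
  maps <- lapply(split(d, factor(d$id, levels = unique(d$id))), function(g) {
    lab <- g[g$channel != 0L, , drop = FALSE]
    if (any(diff(lab$pos) <= 0))
      stop(sprintf("unsorted label positions in map %s (line %d)",
                   g$id[1], lab$line[which(diff(lab$pos) <= 0)[1] + 1]))
    label_map(g$id[1], g$len[1], lab$pos, channel = max(1L, lab$channel[1]))
  })
  maps[unique(d$id)]
}

## ---- BED gap intervals -------------------------------------------------

#' Read / write gap intervals as BED
#'
#' Plain 0-based half-open BED3 (chrom, start, end), one record per gap.
#'
#' @param gaps Named list of [gap_intervals()] (names = map ids), or a
#'   single `gap_intervals` data.frame with `chrom` supplied.
#' @param path File path.
#' @param chrom Chromosome name used when `gaps` is a bare data.frame.
#' @return `read_gaps_bed` returns a named list of `gap_intervals`.
#' @export
write_gaps_bed <- function(gaps, path, chrom = "map") {
  if (is.data.frame(gaps)) gaps <- stats::setNames(list(gaps), chrom)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(gaps)) {
    g <- gaps[[nm]]
    if (nrow(g))
      writeLines(sprintf("%s\t%.0f\t%.0f", nm, g$start, g$end), con)
  }
  invisible(path)
}

#' @rdname write_gaps_bed
#' @export
read_gaps_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(list())
  f <- strsplit(lines, "\t")
  d <- data.frame(chrom = vapply(f, `[`, "", 1),
                  start = as.numeric(vapply(f, `[`, "", 2)),
                  end = as.numeric(vapply(f, `[`, "", 3)))
  lapply(split(d, factor(d$chrom, levels = unique(d$chrom))),
         function(g) gap_intervals(g$start, g$end))
}
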