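#' Label maps: ordered nick-label positions along a DNA segment
#'
#' A label map is the universal currency of the pipeline: an identifier,
#' a segment length, and a strictly increasing vector of 0-based label
#' positions. In silico digests may carry per-label strand annotation;
#' measured maps (molecules, consensus maps) do not.
#'
#' @param id Character scalar identifier.
#' @param length_bp Non-negative integer segment length.
#' @param positions Strictly increasing integer positions,
#'   `0 <= p < length_bp`.
#' @param strands Optional per-label `"+"`/`"-"` vector (in silico maps
#'   only).
#' @param channel Integer label channel (single-channel dialect; 1).
#'
#' @return An object of class `label_map`.
#' @export
label_map <- function(id, length_bp, positions = integer(0),
                      strands = NULL, channel = 1L) {
  positions <- as.numeric(positions)
  length_bp <- as.numeric(length_bp)
  stopifnot(length(id) == 1L, length_bp >= 0)
  if (length(positions)) {
    if (any(positions < 0) || any(positions >= length_bp))
      stop("label positions must satisfy 0 <= p < length_bp")
    if (any(diff(positions) <= 0))
      stop("label positions must be strictly increasing")
  }
  if (!is.null(strands)) {
    stopifnot(length(strands) == length(positions),
              all(strands %in% c("+", "-")))
  }
  structure(list(id = as.character(id), length_bp = length_bp,
                 positions = positions, strands = strands,
                 channel = as.integer(channel)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %d labels over %.0f bp\n",
              x$id, length(x$positions), x$length_bp))
  invisible(x)
}

#' @export
length.label_map <- function(x) length(x$positions)

#' Mirror a label map end-for-end
#'
#' Reverses label order and mirrors positions (`p -> length_bp - 1 - p`)
#' so the map reads in the opposite direction; strands flip. Applying
#' the transform twice restores the input.
#'
#' @param x A [label_map()].
#' @return The mirrored `label_map`.
#' @export
reverse_map <- function(x) {
  pos <- rev(x$length_bp - 1 - x$positions)
  str <- if (is.null(x$strands)) NULL else
    rev(ifelse(x$strands == "+", "-", "+"))
  label_map(x$id, x$length_bp, pos, str, x$channel)
}

#' Extract the sub-map over a half-open interval
#'
#' Labels in `[from, to)` are kept and re-coordinated to start at 0.
#'
#' @param x A [label_map()].
#' @param from,to 0-based half-open interval bounds.
#' @param id Identifier for the slice.
#' @return A `label_map` of length `to - from`.
#' @export
slice_map <- function(x, from, to, id = x$id) {
  stopifnot(from >= 0, to > from)
  keep <- x$positions >= from & x$positions < to
  label_map(id, to - from, x$positions[keep] - from,
            if (is.null(x$strands)) NULL else x$strands[keep], x$channel)
}

#' Gap intervals
#'
#' 0-based half-open intervals of unknown ("N") sequence on the same
#' coordinate system as the owning label map; disjoint and sorted.
#'
#' @param start,end Integer vectors of equal length.
#' @return A data.frame with columns `start`, `end`.
#' @export
gap_intervals <- function(start = integer(0), end = integer(0)) {
  stopifnot(length(start) == length(end))
  d <- data.frame(start = as.numeric(start), end = as.numeric(end))
  d <- d[order(d$start), , drop = FALSE]
  if (nrow(d)) {
    stopifnot(all(d$start >= 0), all(d$end > d$start))
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("gap intervals must be disjoint")
  }
  rownames(d) <- NULL
  d
}

#' Reference arm
#'
#' A subtelomere window's label map plus its N-gap annotation and
#' landmark coordinates, oriented so position increases toward the
#' telomere. `tel_end_bp` is the end of real (non-N) reference
#' sequence: the window end minus any terminal N run. `arm_end_bp` is
#' the annotated chromosome end including the terminal gap pad, so
#' `arm_end_bp - tel_end_bp` is the terminal gap length.
#'
#' @param arm Arm name, e.g. `"3q"`.
#' @param map [label_map()] over the window.
#' @param gaps [gap_intervals()] in window coordinates.
#' @param window_bp Window size, bp.
#' @param tel_end_bp End of non-N reference sequence.
#' @param arm_end_bp Annotated chromosome end (window end).
#' @param onecopy_interval Two-element numeric `c(start, end)` marking
#'   the 1-copy anchor DNA, centromeric of all duplicated material.
#' @return An object of class `reference_arm`.
#' @export
reference_arm <- function(arm, map, gaps = gap_intervals(),
                          window_bp = map$length_bp,
                          tel_end_bp = map$length_bp,
                          arm_end_bp = map$length_bp,
                          onecopy_interval = c(0, tel_end_bp)) {
  stopifnot(window_bp > 0, tel_end_bp <= map$length_bp,
            arm_end_bp >= tel_end_bp,
            length(onecopy_interval) == 2,
            onecopy_interval[1] < onecopy_interval[2])
  structure(list(arm = arm, map = map, gaps = gaps,
                 window_bp = window_bp, tel_end_bp = tel_end_bp,
                 arm_end_bp = arm_end_bp,
                 onecopy_interval = as.numeric(onecopy_interval)),
            class = "reference_arm")
}

#' @export
print.reference_arm <- function(x, ...) {
  cat(sprintf(
    "<reference_arm> %s: %d labels, window %.0f bp, tel end %.0f, terminal gap %.0f bp\n",
    x$arm, length(x$map$positions), x$window_bp, x$tel_end_bp,
    x$arm_end_bp - x$tel_end_bp))
  invisible(x)
}
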