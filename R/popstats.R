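## Population-level statistics of paralogy-block presence: per-arm
## per-super-population frequency tables, one-way ANOVA across the
## super-populations and Bonferroni correction.

#' Block frequency table by arm and super-population
#'
#' Frequency = genomes carrying the block / genomes with at least one
#' anchored map for the arm, per super-population; raw numerators and
#' denominators are kept alongside.
#'
#' @param presence Output of [presence_matrix()] with an added
#'   `superpop` column.
#' @param block Column name of the block (or group) to tabulate.
#' @return data.frame with one row per arm: frequency, carrier and
#'   total columns per super-population.
#' @export
block_frequency_table <- function(presence, block) {
  stopifnot(block %in% names(presence), "superpop" %in% names(presence))
  pops <- sort(unique(presence$superpop))
  arms <- sort(unique(presence$arm))
  out <- data.frame(arm = arms)
  for (sp in pops) {
    freq <- num <- den <- numeric(length(arms))
    for (k in seq_along(arms)) {
      sub <- presence[presence$arm == arms[k] & presence$superpop == sp, ]
      den[k] <- nrow(sub)
      num[k] <- sum(sub[[block]])
      freq[k] <- if (den[k] > 0) num[k] / den[k] else NA_real_
    }
    out[[paste0(sp, "_freq")]] <- freq
    out[[paste0(sp, "_carriers")]] <- num
    out[[paste0(sp, "_total")]] <- den
  }
  out
}

#' One-way ANOVA of block presence across super-populations
#'
#' Presence is one 0/1 indicator per genome-arm; the test asks whether
#' its mean differs between super-populations. Degenerate inputs (no
#' variance at all) return an NA-flagged result rather than a test.
#'
#' @param presence Logical/0-1 vector, one element per genome.
#' @param groups Super-population factor, parallel to `presence`.
#' @param block,arm Labels carried through to the result row.
#' @return One-row data.frame: `block`, `arm`, `F`, `p`, `n`,
#'   `degenerate`.
#' @export
anova_by_superpop <- function(presence, groups, block = NA, arm = NA) {
  groups <- droplevels(as.factor(groups))
  y <- as.numeric(presence)
  if (nlevels(groups) < 2)
    stop("ANOVA needs at least two super-population groups")
  if (any(table(groups) < 2))
    stop("every group needs at least two observations")
  if (stats::var(y) == 0)
    return(data.frame(block = block, arm = arm, F = NA_real_,
                      p = NA_real_, n = length(y), degenerate = TRUE))
  fit <- stats::aov(y ~ groups)
  s <- summary(fit)[[1]]
  data.frame(block = block, arm = arm, F = s[["F value"]][1],
             p = s[["Pr(>F)"]][1], n = length(y), degenerate = FALSE)
}

#' Bonferroni correction over a family of arm-level tests
#'
#' Adjusted p = min(1, p * m); by default m is the number of
#' non-degenerate tests in the family (one per arm tested for the
#' block). Significance is called at alpha after adjustment.
#'
#' @param results data.frame of [anova_by_superpop()] rows.
#' @param m Family size; defaults to the number of non-degenerate
#'   rows.
#' @param alpha Significance level (0.05).
#' @return `results` with `m`, `p_adj`, `significant` columns.
#' @export
bonferroni_adjust <- function(results, m = NULL, alpha = 0.05) {
  if (is.null(m)) m <- sum(!results$degenerate & !is.na(results$p))
  results$m <- m
  results$p_adj <- pmin(1, results$p * m)
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  results
}
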