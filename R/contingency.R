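# Exact 2x2 contingency statistics and seizure-incidence summaries.
# fisher_exact is the Fisher engine used by the enrichment and shift
# modules as well.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by the probability-mass rule: conditioning on the
#' margins, the p value sums the hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table
#' (with a `1 + 1e-7` factor guarding floating-point ties).
#' Probabilities are computed through log-gamma for overflow safety.  The
#' odds ratio is the sample `ad/bc`, reported as `Inf`, `0` or `NaN` when
#' cells are zero.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major `a, b, c, d`)
#'   of non-negative integer counts; not all zero.
#' @return A list with `odds_ratio`, `p` and the observed-table
#'   hypergeometric probability `prob`.
#' @export
fisher_exact <- function(table) {
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(table, 2L, byrow = TRUE)
  if (!all(dim(table) == c(2L, 2L)))
    stop_fmt("fisher_exact needs a 2x2 table")
  if (any(table < 0) || any(table != floor(table)))
    stop_fmt("cells must be non-negative integers")
  if (sum(table) == 0L) stop_fmt("all-zero table")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  m <- a + b          # row 1 total
  n2 <- c_ + d        # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
    lgamma(n2 + 1) - lgamma(k - x + 1) - lgamma(n2 - k + x + 1) -
    (lgamma(m + n2 + 1) - lgamma(k + 1) - lgamma(m + n2 - k + 1))
  prob <- exp(logp)
  obs <- prob[x == a]
  p <- min(sum(prob[prob <= obs * (1 + 1e-7)]), 1)
  odds <- (a * d) / (b * c_)
  list(odds_ratio = odds, p = p, prob = obs)
}

#' Seizure incidence summary
#'
#' Per-group counts of tested and responding (seizing) animals with the
#' percent incidence rounded to the nearest integer, half away from zero.
#'
#' @param seizing named integer vector (or list) of seizing animals per
#'   group.
#' @param tested named integer vector of animals tested per group (names
#'   matching `seizing`).
#' @return A data.frame with `group`, `n_tested`, `n_seizing`,
#'   `percent`.
#' @export
incidence <- function(seizing, tested) {
  seizing <- unlist(seizing)
  tested <- unlist(tested)[names(seizing) %||% seq_along(seizing)]
  if (any(tested == 0)) stop_fmt("group with zero animals tested")
  if (any(seizing < 0 | seizing > tested))
    stop_fmt("seizing counts must lie in [0, tested]")
  data.frame(
    group = names(seizing) %||% as.character(seq_along(seizing)),
    n_tested = as.integer(tested),
    n_seizing = as.integer(seizing),
    percent = as.integer(round_half_away(100 * seizing / tested)),
    stringsAsFactors = FALSE, row.names = NULL)
}

.STAGES <- c("none", "WR", "clonic", "tonic")

#' Seizure severity table by maximal stage
#'
#' Summarizes per-animal records under the maximal-stage convention: each
#' animal contributes only the most severe stage it reached (wild running
#' < clonic < tonic), so the stage counts partition the seizing animals.
#'
#' @param records data.frame with columns `animal_id`, `group` and
#'   `max_stage` (one of `none`, `WR`, `clonic`, `tonic`).
#' @return A data.frame with one row per group x stage (stages ordered
#'   WR < clonic < tonic): `group`, `stage`, `count`, `n_tested`,
#'   `percent`, plus overall seizing counts in
#'   `attr(, "incidence")`.
#' @export
severity_table <- function(records) {
  required <- c("animal_id", "group", "max_stage")
  if (!all(required %in% names(records)))
    stop_fmt("records need columns %s", paste(required, collapse = ", "))
  if (anyDuplicated(records$animal_id))
    stop_fmt("animal '%s' recorded more than once",
             records$animal_id[duplicated(records$animal_id)][1L])
  if (!all(records$max_stage %in% .STAGES))
    stop_fmt("unknown stage '%s'",
             setdiff(records$max_stage, .STAGES)[1L])
  groups <- unique(records$group)
  stages <- .STAGES[-1L]
  rows <- lapply(groups, function(g) {
    rec <- records[records$group == g, , drop = FALSE]
    nt <- nrow(rec)
    cnt <- vapply(stages, function(s) sum(rec$max_stage == s), integer(1L))
    data.frame(group = g, stage = factor(stages, levels = stages),
               count = cnt, n_tested = nt,
               percent = as.integer(round_half_away(100 * cnt / nt)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  seiz <- vapply(groups, function(g)
    sum(records$group == g & records$max_stage != "none"), integer(1L))
  nt <- vapply(groups, function(g) sum(records$group == g), integer(1L))
  attr(out, "incidence") <- incidence(stats::setNames(seiz, groups),
                                      stats::setNames(nt, groups))
  out
}
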