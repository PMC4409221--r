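# Position-weighted off-target scoring and candidate ranking.

#' Position-weighted mismatch score of one off-target site
#'
#' The likelihood of a stable sgRNA/DNA heteroduplex decreases the closer a
#' mismatch lies to the PAM. Each mismatch at 1-based position `pos`
#' (counted from the protospacer 5' end; position `protospacer_length` is
#' PAM-adjacent) contributes `base^pos`, and the site score is the sum over
#' all mismatches. The default base 1.2 was determined empirically. A
#' perfect match scores 0.
#'
#' @param positions Integer vector of mismatch positions (may be empty).
#' @param base Base of the power expression (> 1; default 1.2).
#' @param protospacer_length Upper bound for valid positions (default 20).
#' @return Numeric score.
#' @examples
#' off_target_score(c(1, 2, 3, 4))  # 6.4416
#' @export
off_target_score <- function(positions, base = 1.2, protospacer_length = 20L) {
  if (length(positions) == 0L) return(0)
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L) ||
      any(positions > protospacer_length)) {
    stop(sprintf("mismatch positions must lie in [1, %d]", protospacer_length))
  }
  sum(base^positions)
}

#' Fill mismatch scores on a hit table
#'
#' @param hits Hit `data.frame` from [search_off_targets()].
#' @param cfg A [pattern_config()].
#' @return `hits` with `mismatch_score` populated.
#' @export
score_hits <- function(hits, cfg = pattern_config()) {
  mp <- mismatch_positions(hits)
  hits$mismatch_score <- vapply(mp, off_target_score, numeric(1),
                                base = cfg$score_base,
                                protospacer_length = cfg$protospacer_length)
  hits
}

#' Aggregate target-site score of one candidate
#'
#' Combines the number of retained off-target sites, the distribution of
#' their mismatches and their proximity to exons into a single score:
#' the sum, over off-targets with an assigned exon, of
#' `log10(dist) + mismatch_score / total_off_targets`, minus
#' `total_off_targets`. `total_off_targets` counts *all* retained
#' off-targets (exon-less sites act through the subtracted count), while
#' the sum runs only over exon-associated sites. `dist` is clamped to a
#' minimum of 1 before the logarithm so that overlap (distance 0) stays
#' finite. Higher scores indicate better (more specific) candidates; a
#' candidate with no off-targets scores 0.
#'
#' @param off_targets Annotated, scored hit `data.frame` (columns
#'   `mismatch_score` and `distance`); zero rows allowed.
#' @return Numeric score.
#' @examples
#' ot <- data.frame(mismatch_score = 6.4416, distance = 1000)
#' site_rank_score(ot)  # log10(1000) + 6.4416 - 1 = 8.4416
#' @export
site_rank_score <- function(off_targets) {
  n <- nrow(off_targets)
  if (is.null(n) || n == 0L) return(0)
  stopifnot(!any(is.na(off_targets$mismatch_score)))
  with_exon <- !is.na(off_targets$distance)
  if (!any(with_exon)) return(0 - n)
  d <- pmax(off_targets$distance[with_exon], 1)
  sum(log10(d) + off_targets$mismatch_score[with_exon] / n) - n
}

#' Rank candidate sites
#'
#' Orders a site table by descending `rank_score`; ties are broken by fewer
#' `total_off_targets`, then smaller `query_start`, then `+` strand first.
#' `site_id` labels `T1`, `T2`, ... are assigned in final order.
#'
#' @param sites `data.frame` with at least `rank_score`,
#'   `total_off_targets`, `query_start` and `strand` columns.
#' @return The reordered `data.frame` with `rank` and `site_id` filled in.
#' @export
rank_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    sites$rank <- integer(0)
    return(sites)
  }
  o <- order(-sites$rank_score, sites$total_off_targets, sites$query_start,
             match(sites$strand, c("+", "-")))
  sites <- sites[o, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  sites$site_id <- paste0("T", sites$rank)
  rownames(sites) <- NULL
  sites
}
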