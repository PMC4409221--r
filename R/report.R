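# End-to-end pipeline and report writers (FASTA, TSV, BED custom track).

#' Run the full target-prediction pipeline
#'
#' Chains candidate discovery in the query, genome-wide off-target search
#' per candidate, nearest-exon annotation, mismatch and aggregate scoring,
#' ranking, and cloning-oligo design. The presumed on-target hit of each
#' candidate (best alignment, or the hit overlapping `query_locus` when
#' given) is recorded as the site's genomic locus and excluded from its
#' off-target list.
#'
#' @param query Query sequence string or FASTA path.
#' @param genome Genome FASTA path or named character vector.
#' @param exon_bed Exon BED path, a `GRanges` from [load_exons()], a data
#'   frame for [exons_from_df()], or `NULL` for no annotation.
#' @param cfg A [pattern_config()].
#' @param output_dir If non-NULL, write `candidates.fasta`,
#'   `results.tsv` and (when loci are known) `track.bed` there.
#' @param query_locus Optional `list(chrom =, start =, end =)` locating the
#'   query on the genome (0-based half-open).
#' @param verbose Log per-stage counts via [message()].
#' @return An object of class `run_report`: a list with `cfg`, `sites` (the
#'   ranked candidate table), `off_targets` (named list of annotated hit
#'   tables keyed by site id), `counts` and `manifest` (written files).
#' @export
run_pipeline <- function(query, genome, exon_bed = NULL,
                         cfg = pattern_config(), output_dir = NULL,
                         query_locus = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pattern_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  q <- stage("read query", read_query(query))
  candidates <- stage("site discovery", find_candidate_sites(q, cfg))
  say("site discovery: %d candidate(s)", nrow(candidates))

  exons <- stage("exon annotation", {
    if (is.null(exon_bed)) NULL
    else if (methods::is(exon_bed, "GRanges")) exon_bed
    else if (is.data.frame(exon_bed)) exons_from_df(exon_bed)
    else load_exons(exon_bed)
  })

  sites <- candidates
  sites$rank_score <- numeric(nrow(sites))
  sites$total_off_targets <- integer(nrow(sites))
  sites$oligo_forward <- character(nrow(sites))
  sites$oligo_reverse <- character(nrow(sites))
  sites$on_chrom <- rep(NA_character_, nrow(sites))
  sites$on_start <- rep(NA_integer_, nrow(sites))
  sites$on_end <- rep(NA_integer_, nrow(sites))
  sites$on_strand <- rep(NA_character_, nrow(sites))
  off_lists <- vector("list", nrow(sites))

  if (nrow(sites) > 0L) {
    index <- stage("seed index", build_seed_index(genome, cfg))
    for (i in seq_len(nrow(sites))) {
      hits <- stage("off-target search",
                    search_off_targets(sites[i, ], index, cfg,
                                       on_target_locus = query_locus,
                                       keep_on_target = TRUE))
      on <- hits[hits$is_on_target, , drop = FALSE]
      off <- hits[!hits$is_on_target, , drop = FALSE]
      if (nrow(on) > 0L) {
        sites$on_chrom[i] <- on$chrom[1L]
        sites$on_start[i] <- on$start[1L]
        sites$on_end[i] <- on$end[1L]
        sites$on_strand[i] <- on$strand[1L]
      }
      off <- stage("exon annotation",
                   annotate_hits(off, exons, cfg$exon_assignment_radius))
      off <- stage("scoring", score_hits(off, cfg))
      sites$rank_score[i] <- site_rank_score(off)
      sites$total_off_targets[i] <- nrow(off)
      ol <- stage("oligo design",
                  design_oligos(sites$protospacer[i], cfg$oligo_gg_mode))
      sites$oligo_forward[i] <- ol$forward
      sites$oligo_reverse[i] <- ol$reverse
      off_lists[[i]] <- off
      say("candidate %d/%d: %d off-target(s), %d annotated",
          i, nrow(sites), nrow(off), sum(!is.na(off$distance)))
    }
  }

  sites <- rank_sites(sites)
  # reorder the per-site hit tables to the ranked order
  if (nrow(sites) > 0L) {
    key_new <- paste(sites$query_start, sites$strand)
    key_old <- paste(candidates$query_start, candidates$strand)
    off_lists <- off_lists[match(key_new, key_old)]
    names(off_lists) <- sites$site_id
  } else {
    off_lists <- stats::setNames(list(), character(0))
  }

  report <- structure(
    list(cfg = cfg,
         sites = sites,
         off_targets = off_lists,
         counts = c(candidates = nrow(sites),
                    off_targets = sum(sites$total_off_targets)),
         manifest = character(0)),
    class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(output_dir, "candidates.fasta")
    tsv <- file.path(output_dir, "results.tsv")
    write_candidates_fasta(report, fa)
    write_full_tsv(report, tsv)
    report$manifest <- c(fasta = fa, tsv = tsv)
    if (any(!is.na(report$sites$on_chrom))) {
      bed <- file.path(output_dir, "track.bed")
      write_track_bed(report, bed)
      report$manifest <- c(report$manifest, bed = bed)
    }
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: %d candidate site(s), %d off-target(s) total\n",
              x$counts[["candidates"]], x$counts[["off_targets"]]))
  if (nrow(x$sites) > 0L) {
    show <- x$sites[, c("site_id", "query_start", "query_end", "strand",
                        "protospacer", "pam", "rank_score",
                        "total_off_targets")]
    print(utils::head(show, 10L), row.names = FALSE)
    if (nrow(x$sites) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Write ranked candidate sites as FASTA
#'
#' One record per site, header `T<rank>|<query_start+1>-<query_end>|<strand>`
#' (1-based inclusive coordinates), sequence protospacer plus PAM.
#'
#' @param report A `run_report` (or its `sites` table).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates_fasta <- function(report, path) {
  sites <- if (inherits(report, "run_report")) report$sites else report
  if (nrow(sites) == 0L) {
    warning("no candidate sites; writing empty FASTA")
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(paste0(sites$protospacer, sites$pam))
  names(seqs) <- sprintf("%s|%d-%d|%s", sites$site_id,
                         sites$query_start + 1L, sites$query_end,
                         sites$strand)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Lowercase the mismatched positions of a site sequence.
.highlight_mismatches <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  ch <- .chars(seq)
  ch[positions] <- tolower(ch[positions])
  paste(ch, collapse = "")
}

#' Write the full results TSV
#'
#' Human-facing report: coordinates are 1-based inclusive. Each candidate
#' contributes one `site` row (id, query coordinates, strand, protospacer,
#' PAM, aggregate score, off-target count, oligo pair) followed by one
#' `offtarget` row per hit (genomic coordinates, strand, site sequence with
#' mismatched bases lowercased, mismatch count and score, exon distance or
#' NA, location category, gene name and id). Scores carry 4 decimals.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_full_tsv <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  lines <- c(
    sprintf("# pattern=%s offtarget_pam=%s core=%d/%d total_mm=%d radius=%d",
            render_pattern(report$cfg), report$cfg$offtarget_pam,
            report$cfg$core_length, report$cfg$max_core_mismatches,
            report$cfg$max_total_mismatches,
            report$cfg$exon_assignment_radius),
    "# site coordinates: 1-based inclusive on the query/genome",
    paste("record", "site_id", "chrom_or_query", "start", "end", "strand",
          "sequence", "pam", "score", "mismatches_or_count",
          "distance_or_oligo_f", "category_or_oligo_r", "gene_name",
          "gene_id", sep = "\t"))
  sites <- report$sites
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    lines <- c(lines, paste(
      "site", s$site_id, "query", s$query_start + 1L, s$query_end, s$strand,
      s$protospacer, s$pam, sprintf("%.4f", s$rank_score),
      s$total_off_targets, s$oligo_forward, s$oligo_reverse, "NA", "NA",
      sep = "\t"))
    off <- report$off_targets[[s$site_id]]
    if (is.null(off) || nrow(off) == 0L) next
    mp <- mismatch_positions(off)
    for (j in seq_len(nrow(off))) {
      lines <- c(lines, paste(
        "offtarget", s$site_id, off$chrom[j], off$start[j] + 1L, off$end[j],
        off$strand[j], .highlight_mismatches(off$site_sequence[j], mp[[j]]),
        off$pam_observed[j], sprintf("%.4f", off$mismatch_score[j]),
        off$n_mismatches[j],
        ifelse(is.na(off$distance[j]), "NA", off$distance[j]),
        off$category[j],
        ifelse(is.na(off$gene_name[j]), "NA", off$gene_name[j]),
        ifelse(is.na(off$gene_id[j]), "NA", off$gene_id[j]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the UCSC-style custom-track BED
#'
#' BED6 with 0-based half-open genomic coordinates of each site's on-target
#' locus; the name is the site id and the score is the aggregate site score
#' min-max rescaled to 0-1000 over the run (a single site maps to 1000).
#' Sites whose genomic locus is unknown are skipped with a warning.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track_bed <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  sites <- report$sites
  known <- !is.na(sites$on_chrom)
  if (any(!known)) {
    warning(sum(!known), " site(s) without a genomic locus skipped in BED")
  }
  sites <- sites[known, , drop = FALSE]
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  rng <- range(sites$rank_score)
  bed_score <- if (diff(rng) == 0) {
    rep(1000L, nrow(sites))
  } else {
    as.integer(round(1000 * (sites$rank_score - rng[1]) / diff(rng)))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   sites$on_chrom, sites$on_start, sites$on_end,
                   sites$site_id, bed_score, sites$on_strand)
  writeLines(lines, path)
  invisible(path)
}
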