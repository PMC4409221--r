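# Nearest-exon assignment and exonic/intronic/intergenic classification.

#' Load an exon annotation from a BED file
#'
#' Expects a BED6-like file with at least four whitespace-separated columns:
#' chrom, start, end (0-based half-open), name, and optionally score and
#' strand. The name field carries `gene_name<delim>gene_id`; when the
#' delimiter is absent the whole field is used for both. Lines beginning
#' with `#`, `track` or `browser` are skipped. Malformed lines are rejected
#' with their line numbers.
#'
#' @param bed_path Path to the BED file.
#' @param name_delim Delimiter between gene name and gene identifier in the
#'   name column (default `"|"`).
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_name` and
#'   `gene_id`. An empty file yields an empty `GRanges`.
#' @export
load_exons <- function(bed_path, name_delim = "|") {
  if (!file.exists(bed_path)) stop("exon BED file not found: ", bed_path)
  lines <- readLines(bed_path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges(gene_name = character(0),
                                  gene_id = character(0)))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  ncol <- vapply(fields, length, integer(1))
  bad <- idx[ncol < 4L]
  if (length(bad) > 0) {
    stop("BED line(s) with fewer than 4 columns: line ",
         paste(bad, collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_s <- vapply(fields, `[[`, character(1), 2L)
  end_s <- vapply(fields, `[[`, character(1), 3L)
  name <- vapply(fields, `[[`, character(1), 4L)
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "*"
  }, character(1))
  suppressWarnings({
    start0 <- as.integer(start_s)
    end0 <- as.integer(end_s)
  })
  bad <- idx[is.na(start0) | is.na(end0)]
  if (length(bad) > 0) {
    stop("BED line(s) with non-integer coordinates: line ",
         paste(bad, collapse = ", "))
  }
  bad <- idx[start0 >= end0]
  if (length(bad) > 0) {
    stop("BED line(s) with start >= end (zero-length exon): line ",
         paste(bad, collapse = ", "))
  }
  parts <- strsplit(name, name_delim, fixed = TRUE)
  gene_name <- vapply(parts, `[[`, character(1), 1L)
  gene_id <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else p[[1L]],
                    character(1))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    gene_name = gene_name, gene_id = gene_id)
}

#' Construct an exon annotation from a data frame
#'
#' Convenience companion to [load_exons()] for in-memory fixtures. Expects
#' 0-based half-open `start`/`end` columns plus `chrom`, `gene_name`,
#' `gene_id`.
#'
#' @param df A data frame.
#' @return A [GenomicRanges::GRanges] as from [load_exons()].
#' @export
exons_from_df <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges(gene_name = character(0),
                                  gene_id = character(0)))
  }
  stopifnot(all(df$start < df$end))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*",
    gene_name = df$gene_name, gene_id = df$gene_id)
}

# Gap distance in half-open coordinates between a hit interval and every
# exon of a GRanges: max(0, hit_start - exon_end, exon_start - hit_end).
# Abutting intervals get 0; annotation ignores strand on both sides.
.gap_distances <- function(hit_chrom, hit_start0, hit_end0, exons) {
  on_chrom <- as.character(GenomicRanges::seqnames(exons)) == hit_chrom
  ex_start0 <- GenomicRanges::start(exons) - 1L
  ex_end0 <- GenomicRanges::end(exons)
  d <- pmax(0L, hit_start0 - ex_end0, ex_start0 - hit_end0)
  d[!on_chrom] <- NA_integer_
  d
}

#' Assign the closest exon to an off-target hit
#'
#' Returns the exon minimising the interval gap distance (0 on overlap or
#' when directly abutting). Only exons strictly closer than `radius` on the
#' same chromosome are considered; otherwise the distance and gene fields
#' are `NA`. Equidistant ties go to the exon with the lower start, then the
#' lexicographically smaller `gene_id`. Hit strand is ignored.
#'
#' @param hit A single hit: one row of a [search_off_targets()] result, or a
#'   `list(chrom =, start =, end =)` in 0-based half-open coordinates.
#' @param exons A `GRanges` from [load_exons()] / [exons_from_df()].
#' @param radius Assignment radius in bases (default 100000; strict).
#' @return A list with `distance` (integer or NA), `gene_name`, `gene_id`,
#'   and `category` (`"exonic"`, `"intronic"` or `"intergenic"`).
#' @export
closest_exon <- function(hit, exons, radius = 100000L) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit[1L, ])
  }
  ann <- .annotate_one(hit$chrom, hit$start, hit$end, exons, radius)
  ann
}

.annotate_one <- function(chrom, start0, end0, exons, radius) {
  na_ann <- list(distance = NA_integer_, gene_name = NA_character_,
                 gene_id = NA_character_, category = "intergenic")
  if (length(exons) == 0L) return(na_ann)
  d <- .gap_distances(chrom, start0, end0, exons)
  elig <- which(!is.na(d) & d < radius)
  if (length(elig) == 0L) return(na_ann)
  ex_start <- GenomicRanges::start(exons)[elig]
  gid <- S4Vectors::mcols(exons)$gene_id[elig]
  pick <- elig[order(d[elig], ex_start, gid)[1L]]
  assigned_id <- S4Vectors::mcols(exons)$gene_id[pick]

  overlaps_exon <- any(d == 0L &
                         start0 < GenomicRanges::end(exons) &
                         GenomicRanges::start(exons) - 1L < end0 &
                         as.character(GenomicRanges::seqnames(exons)) == chrom,
                       na.rm = TRUE)
  category <- if (overlaps_exon) {
    "exonic"
  } else {
    # gene span: min exon start .. max exon end over exons of the assigned
    # gene_id (transcript structure is not available from an exon BED)
    same_gene <- S4Vectors::mcols(exons)$gene_id == assigned_id &
      as.character(GenomicRanges::seqnames(exons)) == chrom
    span_start0 <- min(GenomicRanges::start(exons)[same_gene]) - 1L
    span_end0 <- max(GenomicRanges::end(exons)[same_gene])
    if (start0 < span_end0 && span_start0 < end0) "intronic" else "intergenic"
  }
  list(distance = as.integer(d[pick]),
       gene_name = S4Vectors::mcols(exons)$gene_name[pick],
       gene_id = assigned_id,
       category = category)
}

#' Classify the genomic location of a hit
#'
#' `"exonic"` if the hit overlaps any exon; `"intronic"` if it lies within
#' the assigned gene's span (the range of exons sharing the assigned
#' `gene_id`) without touching an exon; `"intergenic"` otherwise, including
#' when no exon falls within the radius.
#'
#' @inheritParams closest_exon
#' @return One of `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
classify_location <- function(hit, exons, radius = 100000L) {
  closest_exon(hit, exons, radius)$category
}

#' Annotate a table of hits with their closest exons
#'
#' @param hits A hit `data.frame` from [search_off_targets()].
#' @param exons A `GRanges` from [load_exons()] / [exons_from_df()], or
#'   `NULL` for no annotation (all distances NA, category intergenic).
#' @param radius Assignment radius in bases.
#' @return `hits` with columns `distance`, `gene_name`, `gene_id`,
#'   `category` appended.
#' @export
annotate_hits <- function(hits, exons, radius = 100000L) {
  n <- nrow(hits)
  hits$distance <- rep(NA_integer_, n)
  hits$gene_name <- rep(NA_character_, n)
  hits$gene_id <- rep(NA_character_, n)
  hits$category <- rep("intergenic", n)
  if (n == 0L || is.null(exons) || length(exons) == 0L) return(hits)
  for (i in seq_len(n)) {
    ann <- .annotate_one(hits$chrom[i], hits$start[i], hits$end[i],
                         exons, radius)
    hits$distance[i] <- ann$distance
    hits$gene_name[i] <- ann$gene_name
    hits$gene_id[i] <- ann$gene_id
    hits$category[i] <- ann$category
  }
  hits
}
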