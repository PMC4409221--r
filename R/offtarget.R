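# Genome-wide off-target enumeration under the core/total mismatch model.
#
# Two engines share one contract: a seed-and-verify engine backed by an
# exact k-mer index with a pigeonhole guarantee, and a brute-force full
# window scan used as the independent oracle in the test-suite.

#' Read a reference genome
#'
#' Accepts a multi-FASTA path or a named character vector of sequences.
#' Sequence names are taken verbatim from FASTA headers up to the first
#' whitespace. All sequences are upper-cased (soft-masked lowercase bases
#' are treated as normal bases).
#'
#' @param x Multi-FASTA path or named character vector.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) == 0L) stop("genome FASTA contains no records: ", x)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("genome must be a FASTA path or a named character vector")
  }
  toupper(x)
}

#' Mismatch positions between two equal-length sequences
#'
#' Positions are 1-based from the 5' end of `a`. Comparison is
#' case-insensitive; any non-ACGT character in `b` (the genomic side)
#' counts as a mismatch even when the letters agree, because an ambiguous
#' genome base cannot be assumed to pair.
#'
#' @param a Reference sequence (e.g. the protospacer).
#' @param b Genomic sequence of the same length.
#' @return Sorted integer vector of mismatch positions (empty if identical).
#' @examples
#' count_mismatches("ACGT", "ACGA")  # 4
#' count_mismatches("ACGT", "NCGT")  # 1
#' @export
count_mismatches <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop(sprintf("sequences differ in length (%d vs %d)", nchar(a), nchar(b)))
  }
  av <- .chars(toupper(a))
  bv <- .chars(toupper(b))
  which(av != bv | !(bv %in% .ACGT))
}

# Partition `core_length` positions into `max_mm + 1` near-equal contiguous
# segments. By pigeonhole, any window with <= max_mm core mismatches matches
# at least one segment exactly.
pigeonhole_segments <- function(core_length, max_mm) {
  n_seg <- max_mm + 1L
  if (core_length < n_seg) {
    stop(sprintf("core of %d bp cannot be split into %d segments",
                 core_length, n_seg))
  }
  base <- core_length %/% n_seg
  sizes <- rep.int(base, n_seg)
  rem <- core_length %% n_seg
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

#' Build an exact k-mer seed index over a genome
#'
#' Indexes every k-mer of the forward strand for each segment size of the
#' pigeonhole partition of the core (`max_core_mismatches + 1` near-equal
#' segments). Minus-strand sites are found by looking up the reverse
#' complement of a segment, so the index logically covers both strands.
#' Any genomic site with at most `max_core_mismatches` mismatches in the
#' core shares at least one exact core segment with the query.
#'
#' @param genome Multi-FASTA path or named character vector.
#' @param cfg A [pattern_config()].
#' @return An object of class `seed_index` carrying the genome, the segment
#'   sizes and the per-chromosome k-mer position maps.
#' @export
build_seed_index <- function(genome, cfg = pattern_config()) {
  stopifnot(inherits(cfg, "pattern_config"))
  seqs <- read_genome(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("cannot index an empty genome")
  }
  sizes <- pigeonhole_segments(cfg$core_length, cfg$max_core_mismatches)
  k_sizes <- sort(unique(sizes))
  kmap <- list()
  for (k in k_sizes) {
    per_chrom <- list()
    for (chrom in names(seqs)) {
      n <- nchar(seqs[[chrom]])
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      kmers <- substring(seqs[[chrom]], starts, starts + k - 1L)
      per_chrom[[chrom]] <- list2env(split(starts, kmers), hash = TRUE)
    }
    kmap[[as.character(k)]] <- per_chrom
  }
  structure(list(genome = seqs, segment_sizes = sizes, kmap = kmap,
                 cfg_core = c(core_length = cfg$core_length,
                              max_core_mismatches = cfg$max_core_mismatches)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("Seed index over %d sequence(s), %s bp total\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  core %d bp split into segments: %s\n",
              x$cfg_core[["core_length"]],
              paste(x$segment_sizes, collapse = "/")))
  invisible(x)
}

#' k-mers queryable from a seed index
#'
#' Returns the set of k-mers of length `k` present on either strand of the
#' indexed genome (forward k-mers plus their reverse complements).
#'
#' @param index A `seed_index`.
#' @param k Segment size present in the index.
#' @return Character vector of k-mers.
#' @export
index_kmers <- function(index, k) {
  stopifnot(inherits(index, "seed_index"))
  m <- index$kmap[[as.character(k)]]
  if (is.null(m)) stop("index holds no k-mers of length ", k)
  fw <- unique(unlist(lapply(m, ls), use.names = FALSE))
  sort(unique(c(fw, revcomp(fw))))
}

# Positions (1-based forward-strand starts) of an exact k-mer in a
# chromosome, or integer(0).
.index_lookup <- function(index, chrom, kmer) {
  m <- index$kmap[[as.character(nchar(kmer))]][[chrom]]
  if (is.null(m)) return(integer(0))
  v <- get0(kmer, envir = m, inherits = FALSE)
  if (is.null(v)) integer(0) else v
}

# --- orientation geometry -------------------------------------------------
#
# A site occupies a forward-strand window of W = L + pam_len bases.
#   "+": window = protospacer then PAM, read as-is.
#   "-": window = revcomp(PAM) then revcomp(protospacer); protospacer
#        position p sits at window offset L + pam_len + 1 - p.

# Extract protospacer and PAM (5'->3' on the PAM strand) from a forward
# window string.
.window_site_seq <- function(win, L, pam_len, strand) {
  if (strand == "+") {
    list(proto = substr(win, 1L, L),
         pam = substr(win, L + 1L, L + pam_len))
  } else {
    list(proto = revcomp(substr(win, pam_len + 1L, pam_len + L)),
         pam = revcomp(substr(win, 1L, pam_len)))
  }
}

# Verify one candidate window start; returns NULL or a hit row (list).
.verify_window <- function(seq, chrom, i, proto, cfg, strand) {
  L <- cfg$protospacer_length
  pam_len <- nchar(cfg$offtarget_pam)
  W <- L + pam_len
  n <- nchar(seq)
  if (i < 1L || i + W - 1L > n) return(NULL)
  win <- substr(seq, i, i + W - 1L)
  ss <- .window_site_seq(win, L, pam_len, strand)
  if (!.pam_matches(ss$pam, cfg$offtarget_pam)) return(NULL)
  mp <- count_mismatches(proto, ss$proto)
  if (length(mp) > cfg$max_total_mismatches) return(NULL)
  if (sum(mp > L - cfg$core_length) > cfg$max_core_mismatches) return(NULL)
  list(chrom = chrom, start = i - 1L, end = i - 1L + W, strand = strand,
       site_sequence = ss$proto, pam_observed = ss$pam,
       mismatch_positions = paste(mp, collapse = ","),
       n_mismatches = length(mp),
       n_core_mismatches = sum(mp > L - cfg$core_length))
}

.empty_hits <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), site_sequence = character(0),
             pam_observed = character(0), mismatch_positions = character(0),
             n_mismatches = integer(0), n_core_mismatches = integer(0),
             mismatch_score = numeric(0), is_on_target = logical(0),
             stringsAsFactors = FALSE)
}

.hits_df <- function(rows) {
  if (length(rows) == 0L) return(.empty_hits())
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
  df$mismatch_score <- NA_real_
  df$is_on_target <- FALSE
  df <- df[order(df$chrom, df$start, match(df$strand, c("+", "-"))), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Candidate input: a row of find_candidate_sites() output or a bare string.
.candidate_proto <- function(candidate, cfg) {
  proto <- if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L, "protospacer" %in% names(candidate))
    candidate$protospacer
  } else if (is.list(candidate) && !is.null(candidate$protospacer)) {
    candidate$protospacer
  } else {
    as.character(candidate)
  }
  proto <- toupper(proto)
  if (nchar(proto) != cfg$protospacer_length) {
    stop(sprintf("protospacer length %d does not match configured %d",
                 nchar(proto), cfg$protospacer_length))
  }
  if (!.is_acgt(proto)) stop("protospacer must be pure ACGT: ", proto)
  proto
}

# Flag the presumed on-target hit. With a known locus, the overlapping hit
# is flagged; otherwise the single best alignment (fewest total mismatches,
# then fewest core mismatches, then lowest (chrom, start)).
.flag_on_target <- function(hits, on_target_locus) {
  if (nrow(hits) == 0L) return(hits)
  if (!is.null(on_target_locus)) {
    loc <- on_target_locus
    hits$is_on_target <- hits$chrom == loc$chrom &
      hits$start < loc$end & hits$end > loc$start
  } else {
    best <- order(hits$n_mismatches, hits$n_core_mismatches,
                  hits$chrom, hits$start)[1L]
    hits$is_on_target[best] <- TRUE
  }
  hits
}

#' Enumerate off-target sites of a candidate (seed-and-verify engine)
#'
#' Returns every genomic window, on either strand, whose protospacer part
#' carries at most `max_core_mismatches` mismatches inside the PAM-proximal
#' core and at most `max_total_mismatches` over the whole protospacer, and
#' whose PAM matches `cfg$offtarget_pam`. Mismatches are counted over the
#' protospacer only; PAM bases are matched by motif, never scored. Windows
#' must lie entirely within one sequence record.
#'
#' The presumed on-target hit — the one overlapping `on_target_locus` when
#' supplied, otherwise the single best alignment — is flagged and, unless
#' `keep_on_target = TRUE`, removed from the returned list. Additional
#' perfect matches elsewhere in the genome remain as off-targets.
#'
#' @param candidate One row of [find_candidate_sites()] output, or a bare
#'   protospacer string (pure ACGT).
#' @param genome_or_index A genome (FASTA path or named character vector) or
#'   a prebuilt [build_seed_index()] object.
#' @param cfg A [pattern_config()].
#' @param on_target_locus Optional `list(chrom =, start =, end =)` (0-based
#'   half-open) locating the query in the genome.
#' @param keep_on_target Keep the flagged on-target row in the result?
#' @return A `data.frame` of hits sorted by `(chrom, start)` with columns
#'   `chrom`, `start`, `end`, `strand`, `site_sequence`, `pam_observed`,
#'   `mismatch_positions` (comma-joined, 1-based from the protospacer 5'
#'   end), `n_mismatches`, `n_core_mismatches`, `mismatch_score` (NA until
#'   scoring) and `is_on_target`.
#' @seealso [brute_force_search()] for the index-free oracle.
#' @export
search_off_targets <- function(candidate, genome_or_index,
                               cfg = pattern_config(),
                               on_target_locus = NULL,
                               keep_on_target = FALSE) {
  stopifnot(inherits(cfg, "pattern_config"))
  proto <- .candidate_proto(candidate, cfg)
  index <- if (inherits(genome_or_index, "seed_index")) {
    ic <- genome_or_index$cfg_core
    if (ic[["core_length"]] != cfg$core_length ||
        ic[["max_core_mismatches"]] != cfg$max_core_mismatches) {
      stop("seed index was built for a different core configuration")
    }
    genome_or_index
  } else {
    build_seed_index(genome_or_index, cfg)
  }
  seqs <- index$genome
  L <- cfg$protospacer_length
  pam_len <- nchar(cfg$offtarget_pam)
  W <- L + pam_len
  sizes <- index$segment_sizes
  core_start <- L - cfg$core_length + 1L
  seg_hi <- core_start - 1L + cumsum(sizes)      # proto position of seg end
  seg_lo <- seg_hi - sizes + 1L                  # proto position of seg start

  rows <- list()
  for (chrom in names(seqs)) {
    seq <- seqs[[chrom]]
    if (nchar(seq) < W) next
    for (strand in c("+", "-")) {
      starts <- integer(0)
      for (r in seq_along(sizes)) {
        seg <- substr(proto, seg_lo[r], seg_hi[r])
        if (strand == "+") {
          pos <- .index_lookup(index, chrom, seg)
          starts <- c(starts, pos - (seg_lo[r] - 1L))
        } else {
          pos <- .index_lookup(index, chrom, revcomp(seg))
          starts <- c(starts, pos - (L + pam_len - seg_hi[r]))
        }
      }
      for (i in unique(starts)) {
        hit <- .verify_window(seq, chrom, i, proto, cfg, strand)
        if (!is.null(hit)) rows[[length(rows) + 1L]] <- hit
      }
    }
  }
  hits <- .hits_df(rows)
  hits <- .flag_on_target(hits, on_target_locus)
  if (!keep_on_target) hits <- hits[!hits$is_on_target, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Enumerate off-target sites by exhaustive window scan (oracle)
#'
#' Same contract as [search_off_targets()], implemented as a vectorised full
#' scan of every window on both strands with no index. Used as the
#' independent oracle when validating the seed-and-verify engine.
#'
#' @inheritParams search_off_targets
#' @param genome A genome (FASTA path or named character vector).
#' @return See [search_off_targets()].
#' @export
brute_force_search <- function(candidate, genome, cfg = pattern_config(),
                               on_target_locus = NULL,
                               keep_on_target = FALSE) {
  stopifnot(inherits(cfg, "pattern_config"))
  proto <- .candidate_proto(candidate, cfg)
  seqs <- read_genome(genome)
  L <- cfg$protospacer_length
  pam_len <- nchar(cfg$offtarget_pam)
  W <- L + pam_len
  core_start <- L - cfg$core_length + 1L
  proto_raw <- charToRaw(proto)
  comp_proto_raw <- charToRaw(revcomp(proto))  # window offsets pam_len+1..W
  pam_allowed <- .motif_allowed(cfg$offtarget_pam)
  # minus-strand window: offset t in 1..pam_len holds the complement of PAM
  # motif position pam_len + 1 - t
  pam_allowed_rc <- lapply(rev(pam_allowed), function(a) {
    chartr("ACGT", "TGCA", a)
  })

  rows <- list()
  for (chrom in names(seqs)) {
    seq <- seqs[[chrom]]
    n <- nchar(seq)
    if (n < W) next
    g <- charToRaw(seq)
    M <- n - W + 1L
    idx0 <- seq_len(M)
    for (strand in c("+", "-")) {
      tot <- integer(M)
      core_ct <- integer(M)
      if (strand == "+") {
        for (j in seq_len(L)) {
          neq <- g[idx0 + (j - 1L)] != proto_raw[j]
          tot <- tot + neq
          if (j >= core_start) core_ct <- core_ct + neq
        }
        pam_ok <- rep(TRUE, M)
        for (t in seq_len(pam_len)) {
          pam_ok <- pam_ok &
            (rawToChar(g[idx0 + (L + t - 1L)], multiple = TRUE) %in%
               pam_allowed[[t]])
        }
      } else {
        for (k in seq_len(L)) {           # window offset pam_len + k
          neq <- g[idx0 + (pam_len + k - 1L)] != comp_proto_raw[k]
          tot <- tot + neq
          p <- L - k + 1L                  # protospacer position
          if (p >= core_start) core_ct <- core_ct + neq
        }
        pam_ok <- rep(TRUE, M)
        for (t in seq_len(pam_len)) {
          pam_ok <- pam_ok &
            (rawToChar(g[idx0 + (t - 1L)], multiple = TRUE) %in%
               pam_allowed_rc[[t]])
        }
      }
      keep <- which(pam_ok & tot <= cfg$max_total_mismatches &
                      core_ct <= cfg$max_core_mismatches)
      for (i in keep) {
        hit <- .verify_window(seq, chrom, i, proto, cfg, strand)
        if (!is.null(hit)) rows[[length(rows) + 1L]] <- hit
      }
    }
  }
  hits <- .hits_df(rows)
  hits <- .flag_on_target(hits, on_target_locus)
  if (!keep_on_target) hits <- hits[!hits$is_on_target, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Mismatch positions of hits as integer vectors
#'
#' @param hits A hit `data.frame` from [search_off_targets()].
#' @return List of sorted integer vectors, one per hit row.
#' @export
mismatch_positions <- function(hits) {
  lapply(hits$mismatch_positions, function(s) {
    if (!nzchar(s)) integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}
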