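# Candidate sgRNA target-site discovery in a query sequence.

#' Read a query sequence
#'
#' Accepts either a path to a FASTA file (the first record is used) or a raw
#' sequence string. Whitespace is stripped; characters are validated against
#' the IUPAC alphabet.
#'
#' @param x Path to a FASTA file, or a DNA sequence string.
#' @return Upper-case sequence string.
#' @export
read_query <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x) && !dir.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) == 0L) stop("query FASTA contains no records: ", x)
    if (length(set) > 1L) {
      warning("query FASTA has ", length(set), " records; using the first")
    }
    return(.normalize_seq(as.character(set[[1]]), "query"))
  }
  .normalize_seq(x, "query")
}

#' Find candidate sgRNA target sites in a query sequence
#'
#' Scans both strands of the query for windows of
#' `protospacer_length + nchar(PAM)` bases whose PAM matches
#' `cfg$discovery_pam` and whose protospacer satisfies the configured 5'/3'
#' dinucleotide constraints. Overlapping and nested sites are all reported.
#' Windows whose protospacer contains a non-ACGT base are excluded, as are
#' windows whose observed PAM has any non-ACGT base.
#'
#' Coordinates are 0-based half-open on the query's forward strand and span
#' protospacer plus PAM regardless of site strand; the `strand` column
#' disambiguates. For a `-` strand site the `protospacer`/`pam` columns give
#' the sequence read 5'->3' on the minus strand (the strand of the PAM).
#'
#' @param query Query sequence (string or FASTA path, see [read_query()]).
#' @param cfg A [pattern_config()].
#' @return A `data.frame` with columns `site_id` (NA until ranking),
#'   `query_start`, `query_end`, `strand`, `protospacer`, `pam`, ordered by
#'   `query_start` then strand (`+` first).
#' @examples
#' cfg <- pattern_config()
#' find_candidate_sites("GGTCAGGGTCAGCAGTCCATCGGAAATT", cfg)
#' @export
find_candidate_sites <- function(query, cfg = pattern_config()) {
  stopifnot(inherits(cfg, "pattern_config"))
  q <- read_query(query)
  L <- cfg$protospacer_length
  pam_len <- nchar(cfg$discovery_pam)
  W <- L + pam_len
  n <- nchar(q)
  empty <- data.frame(site_id = character(0),
                      query_start = integer(0), query_end = integer(0),
                      strand = character(0),
                      protospacer = character(0), pam = character(0),
                      stringsAsFactors = FALSE)
  if (n < W) return(empty)

  starts <- seq_len(n - W + 1L)           # 1-based window starts
  win_proto_fw <- substring(q, starts, starts + L - 1L)
  win_pam_fw <- substring(q, starts + L, starts + W - 1L)
  win_pam_rv_fwdcoords <- substring(q, starts, starts + pam_len - 1L)
  win_proto_rv_fwdcoords <- substring(q, starts + pam_len, starts + W - 1L)

  keep_fw <- .pam_matches(win_pam_fw, cfg$discovery_pam) &
    vapply(win_proto_fw, .is_acgt, logical(1), USE.NAMES = FALSE) &
    .protospacer_constraints_ok(win_proto_fw, cfg)

  proto_rv <- revcomp(win_proto_rv_fwdcoords)
  pam_rv <- revcomp(win_pam_rv_fwdcoords)
  keep_rv <- .pam_matches(pam_rv, cfg$discovery_pam) &
    vapply(proto_rv, .is_acgt, logical(1), USE.NAMES = FALSE) &
    .protospacer_constraints_ok(proto_rv, cfg)

  res <- rbind(
    data.frame(site_id = rep(NA_character_, sum(keep_fw)),
               query_start = starts[keep_fw] - 1L,
               query_end = starts[keep_fw] - 1L + W,
               strand = rep("+", sum(keep_fw)),
               protospacer = win_proto_fw[keep_fw],
               pam = win_pam_fw[keep_fw],
               stringsAsFactors = FALSE),
    data.frame(site_id = rep(NA_character_, sum(keep_rv)),
               query_start = starts[keep_rv] - 1L,
               query_end = starts[keep_rv] - 1L + W,
               strand = rep("-", sum(keep_rv)),
               protospacer = proto_rv[keep_rv],
               pam = pam_rv[keep_rv],
               stringsAsFactors = FALSE))
  res <- res[order(res$query_start, match(res$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# 5'/3' dinucleotide constraints on a vector of protospacers.
.protospacer_constraints_ok <- function(protos, cfg) {
  L <- cfg$protospacer_length
  ok <- rep(TRUE, length(protos))
  if (cfg$five_prime_constraint == "GN") {
    ok <- ok & substr(protos, 1L, 1L) == "G"
  } else if (cfg$five_prime_constraint == "GG") {
    ok <- ok & substr(protos, 1L, 2L) == "GG"
  }
  if (cfg$three_prime_constraint == "GG") {
    ok <- ok & substr(protos, L - 1L, L) == "GG"
  }
  ok
}
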