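# Low-level sequence utilities shared across modules.

# IUPAC nucleotide codes and the set of unambiguous bases each one stands for.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.IUPAC_CODES <- names(.IUPAC)
.ACGT <- c("A", "C", "G", "T")

# Complement table covering the full IUPAC alphabet, both cases.
.COMP_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
.COMP_TO   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; handles the full IUPAC alphabet and preserves case.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GCATTTGTCAATGGATACCCTGG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr(.COMP_FROM, .COMP_TO, x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Match a genomic base against an IUPAC pattern code
#'
#' The pattern base is interpreted as an IUPAC degeneracy code; the genome
#' base is taken literally. Ambiguous *genome* characters (including N)
#' never match any pattern base, so masked or unsequenced regions cannot
#' produce spurious hits. Matching is case-insensitive.
#'
#' @param pattern_base Character vector of IUPAC codes (recycled).
#' @param genome_base Character vector of genome characters.
#' @return Logical vector.
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("N", "N")  # FALSE: genome N is indeterminate
#' @export
iupac_match <- function(pattern_base, genome_base) {
  p <- toupper(pattern_base)
  g <- toupper(genome_base)
  bad <- !(p %in% .IUPAC_CODES)
  if (any(bad)) {
    stop("unknown IUPAC pattern code(s): ",
         paste(unique(p[bad]), collapse = ", "))
  }
  n <- max(length(p), length(g))
  p <- rep_len(p, n)
  g <- rep_len(g, n)
  mapply(function(pb, gb) gb %in% .ACGT && gb %in% .IUPAC[[pb]], p, g,
         USE.NAMES = FALSE)
}

# Split a string into single characters.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TRUE if the string contains only A/C/G/T (upper case assumed).
.is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

# Validate that a sequence uses only IUPAC characters; returns the
# upper-cased sequence or raises an error naming the offending character.
.normalize_seq <- function(x, what = "sequence") {
  x <- toupper(gsub("[ \t\r\n]", "", x))
  bad <- regmatches(x, regexpr(sprintf("[^%s]", paste(.IUPAC_CODES, collapse = "")), x))
  if (length(bad) > 0 && nzchar(bad)) {
    stop(sprintf("%s contains non-IUPAC character '%s'", what, bad))
  }
  x
}

# Expand an IUPAC motif (e.g. "NGG") into a list of allowed ACGT characters
# per position. Genome side is restricted to ACGT by design.
.motif_allowed <- function(motif) {
  lapply(.chars(toupper(motif)), function(cc) .IUPAC[[cc]])
}

# Vectorised check of fixed-length PAM strings against a motif.
.pam_matches <- function(pams, motif) {
  allowed <- .motif_allowed(motif)
  k <- length(allowed)
  ok <- rep(TRUE, length(pams))
  for (t in seq_len(k)) {
    ok <- ok & substr(pams, t, t) %in% allowed[[t]]
  }
  ok
}
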