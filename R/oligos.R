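# Cloning oligo design for the DR274 sgRNA vector (BsaI golden gate).
#
# Annealed oligo pairs leave a TAGG 5' overhang on the forward strand and
# an AAAC 5' overhang on the reverse strand, matching the BsaI-digested
# vector. Efficient T7 in vitro transcription requires the transcript to
# start with GG; protospacers lacking it are fixed by extending or
# substituting the most 5' base(s) with lowercase g.

#' Design a cloning oligo pair for a protospacer
#'
#' GG-fixing first: a protospacer already starting `GG` is left unchanged;
#' one starting `G` but not `GG` gets a single `g` prepended (`extension`)
#' or its second base replaced by `g` (`substitution`); any other start
#' gets `gg` prepended or its first two bases replaced by `gg`. The forward
#' oligo is `TA` plus the fixed protospacer (added/substituted bases in
#' lowercase); the reverse oligo is `AAAC` plus the reverse complement of
#' the fixed protospacer minus its first two bases, all uppercase.
#'
#' @param protospacer Protospacer string, pure ACGT, typically 20 nt.
#' @param mode `"extension"` (default; lengthens the transcribed guide by
#'   1-2 nt) or `"substitution"` (keeps the length, alters identity).
#' @return A list of class `oligo_pair` with elements `forward`, `reverse`,
#'   `modification` (`"none"`, `"extended"` or `"substituted"`) and
#'   `fixed_protospacer`.
#' @examples
#' design_oligos("GCATTTGTCAATGGATACCC")$forward  # "TAgGCATTTGTCAATGGATACCC"
#' @export
design_oligos <- function(protospacer, mode = c("extension", "substitution")) {
  mode <- match.arg(mode)
  stopifnot(is.character(protospacer), length(protospacer) == 1L)
  proto <- toupper(protospacer)
  if (!.is_acgt(proto) || nchar(proto) < 3L) {
    stop("protospacer must be a pure-ACGT string: ", protospacer)
  }
  first2 <- substr(proto, 1L, 2L)
  if (first2 == "GG") {
    fixed <- proto
    modification <- "none"
  } else if (substr(proto, 1L, 1L) == "G") {
    if (mode == "extension") {
      fixed <- paste0("g", proto)
      modification <- "extended"
    } else {
      fixed <- paste0(substr(proto, 1L, 1L), "g", substr(proto, 3L, nchar(proto)))
      modification <- "substituted"
    }
  } else {
    if (mode == "extension") {
      fixed <- paste0("gg", proto)
      modification <- "extended"
    } else {
      fixed <- paste0("gg", substr(proto, 3L, nchar(proto)))
      modification <- "substituted"
    }
  }
  forward <- paste0("TA", fixed)
  reverse <- toupper(paste0("AAAC",
                            revcomp(substr(fixed, 3L, nchar(fixed)))))
  structure(list(forward = forward, reverse = reverse,
                 modification = modification, fixed_protospacer = fixed),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("forward : 5'-%s-3'\n", x$forward))
  cat(sprintf("reverse : 5'-%s-3'\n", x$reverse))
  cat(sprintf("guide   : %s (%s)\n", x$fixed_protospacer, x$modification))
  invisible(x)
}
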