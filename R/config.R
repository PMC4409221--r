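# Run configuration: the pattern grammar and all user-tunable parameters.

.PAM_CHOICES <- c("NGG", "NRG")

#' Run configuration for target-site discovery and off-target search
#'
#' Bundles every tunable of the pipeline: the protospacer length, the PAM
#' motif used when scanning the query (`discovery_pam`) and, independently,
#' the motif accepted at genomic off-target sites (`offtarget_pam`); optional
#' 5'/3' dinucleotide constraints on the protospacer; the PAM-proximal core
#' (seed) length and the two mismatch ceilings of the off-target model; the
#' radius within which an exon is assigned to an off-target; the base of the
#' position-weighted mismatch score; and the GG-fixing mode for cloning
#' oligos.
#'
#' @param protospacer_length Protospacer length in bases (default 20).
#' @param discovery_pam PAM motif for candidate discovery, `"NGG"` or `"NRG"`.
#' @param offtarget_pam PAM motif accepted at off-target sites, selectable
#'   independently of `discovery_pam`.
#' @param five_prime_constraint Identity of the two most-5' protospacer
#'   bases: `"NN"` (free), `"GN"` or `"GG"`.
#' @param three_prime_constraint Identity of the two most-3' (PAM-proximal)
#'   protospacer bases: `"NN"` or `"GG"`.
#' @param core_length Length in bases of the PAM-proximal core (default 12).
#' @param max_core_mismatches Maximum mismatches tolerated inside the core
#'   (default 2).
#' @param max_total_mismatches Maximum mismatches over the whole protospacer
#'   (default 4).
#' @param exon_assignment_radius Maximum distance in bases at which an exon
#'   is assigned to an off-target site (default 100000; strictly closer).
#' @param score_base Base of the per-mismatch power score (fixed at 1.2,
#'   empirically determined; must exceed 1).
#' @param oligo_gg_mode `"extension"` or `"substitution"`: how the 5' GG
#'   required by the T7 promoter is enforced in cloning oligos.
#' @return An object of class `pattern_config`.
#' @examples
#' cfg <- pattern_config()
#' cfg$core_length
#' @export
pattern_config <- function(protospacer_length = 20L,
                           discovery_pam = "NGG",
                           offtarget_pam = "NGG",
                           five_prime_constraint = "NN",
                           three_prime_constraint = "NN",
                           core_length = 12L,
                           max_core_mismatches = 2L,
                           max_total_mismatches = 4L,
                           exon_assignment_radius = 100000L,
                           score_base = 1.2,
                           oligo_gg_mode = c("extension", "substitution")) {
  protospacer_length <- as.integer(protospacer_length)
  core_length <- as.integer(core_length)
  max_core_mismatches <- as.integer(max_core_mismatches)
  max_total_mismatches <- as.integer(max_total_mismatches)
  exon_assignment_radius <- as.integer(exon_assignment_radius)
  oligo_gg_mode <- match.arg(oligo_gg_mode)
  discovery_pam <- match.arg(toupper(discovery_pam), .PAM_CHOICES)
  offtarget_pam <- match.arg(toupper(offtarget_pam), .PAM_CHOICES)
  five_prime_constraint <- match.arg(toupper(five_prime_constraint),
                                     c("NN", "GN", "GG"))
  three_prime_constraint <- match.arg(toupper(three_prime_constraint),
                                      c("NN", "GG"))
  if (protospacer_length < 1L) stop("protospacer_length must be positive")
  if (core_length < 1L || core_length > protospacer_length) {
    stop("core_length must satisfy 0 < core_length <= protospacer_length")
  }
  if (max_core_mismatches < 0L || max_core_mismatches > max_total_mismatches) {
    stop("need 0 <= max_core_mismatches <= max_total_mismatches")
  }
  if (!is.numeric(score_base) || score_base <= 1) {
    stop("score_base must be > 1")
  }
  structure(
    list(protospacer_length = protospacer_length,
         discovery_pam = discovery_pam,
         offtarget_pam = offtarget_pam,
         five_prime_constraint = five_prime_constraint,
         three_prime_constraint = three_prime_constraint,
         core_length = core_length,
         max_core_mismatches = max_core_mismatches,
         max_total_mismatches = max_total_mismatches,
         exon_assignment_radius = exon_assignment_radius,
         score_base = as.numeric(score_base),
         oligo_gg_mode = oligo_gg_mode),
    class = "pattern_config")
}

#' @export
print.pattern_config <- function(x, ...) {
  cat("Target-site configuration\n")
  cat(sprintf("  pattern          : %s\n", render_pattern(x)))
  cat(sprintf("  off-target PAM   : %s\n", x$offtarget_pam))
  cat(sprintf("  5'/3' constraint : %s / %s\n",
              x$five_prime_constraint, x$three_prime_constraint))
  cat(sprintf("  core             : %d bp, <= %d mismatches\n",
              x$core_length, x$max_core_mismatches))
  cat(sprintf("  total mismatches : <= %d\n", x$max_total_mismatches))
  cat(sprintf("  exon radius      : %d bp\n", x$exon_assignment_radius))
  cat(sprintf("  score base       : %g\n", x$score_base))
  cat(sprintf("  oligo GG mode    : %s\n", x$oligo_gg_mode))
  invisible(x)
}

#' Parse a target-site pattern string
#'
#' The pattern grammar is `<IUPAC code><count><PAM motif>`, e.g. `"N20NGG"`:
#' a protospacer of 20 unconstrained bases followed by an NGG PAM. The PAM
#' motif must be one of the supported Cas9 motifs (`NGG`, `NRG`).
#'
#' @param pattern_string Pattern such as `"N20NGG"`.
#' @return A list with elements `protospacer_length` and `discovery_pam`,
#'   suitable for splicing into [pattern_config()].
#' @examples
#' parse_pattern("N20NGG")
#' @export
parse_pattern <- function(pattern_string) {
  stopifnot(is.character(pattern_string), length(pattern_string) == 1L)
  s <- toupper(trimws(pattern_string))
  m <- regexec("^([A-Z])([0-9]+)([A-Z]+)$", s)[[1]]
  if (m[1] == -1L) {
    stop(sprintf("malformed pattern '%s': expected <IUPAC><count><PAM>, e.g. N20NGG",
                 pattern_string))
  }
  parts <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z]+)$", s))[[1]]
  run_code <- parts[2]
  count <- as.integer(parts[3])
  pam <- parts[4]
  if (!(run_code %in% .IUPAC_CODES)) {
    stop(sprintf("malformed pattern '%s': '%s' is not an IUPAC code",
                 pattern_string, run_code))
  }
  bad_pam <- setdiff(.chars(pam), .IUPAC_CODES)
  if (length(bad_pam) > 0) {
    stop(sprintf("malformed pattern '%s': PAM contains non-IUPAC code '%s'",
                 pattern_string, bad_pam[1]))
  }
  if (!(pam %in% .PAM_CHOICES)) {
    stop(sprintf("malformed pattern '%s': unsupported PAM motif '%s' (use %s)",
                 pattern_string, pam, paste(.PAM_CHOICES, collapse = " or ")))
  }
  if (count < 1L) {
    stop(sprintf("malformed pattern '%s': protospacer length must be positive",
                 pattern_string))
  }
  list(protospacer_length = count, discovery_pam = pam)
}

#' Render a configuration back to its pattern string
#'
#' Inverse of [parse_pattern()] for the fields the pattern grammar covers.
#'
#' @param cfg A `pattern_config`.
#' @return Pattern string such as `"N20NGG"`.
#' @export
render_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "pattern_config"))
  sprintf("N%d%s", cfg$protospacer_length, cfg$discovery_pam)
}

#' Read a flat key-value configuration file
#'
#' The file holds one `key: value` pair per line (YAML-style scalars only),
#' keys mirroring the [pattern_config()] argument names. Blank lines and
#' lines starting with `#` are ignored. A `pattern` key is expanded through
#' [parse_pattern()].
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values taking precedence over the file
#'   (e.g. parsed command-line flags).
#' @return A `pattern_config`.
#' @export
read_config_file <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("config line %d is not 'key: value': '%s'", i, lines[i]))
    }
    kv[[m[2]]] <- m[3]
  }
  if (!is.null(kv$pattern)) {
    frag <- parse_pattern(kv$pattern)
    kv$pattern <- NULL
    kv$protospacer_length <- frag$protospacer_length
    kv$discovery_pam <- frag$discovery_pam
  }
  kv[names(overrides)] <- overrides
  int_keys <- c("protospacer_length", "core_length", "max_core_mismatches",
                "max_total_mismatches", "exon_assignment_radius")
  for (k in intersect(names(kv), int_keys)) kv[[k]] <- as.integer(kv[[k]])
  if (!is.null(kv$score_base)) kv$score_base <- as.numeric(kv$score_base)
  do.call(pattern_config, kv)
}
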