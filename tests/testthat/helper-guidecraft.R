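# Shared helpers: random sequence, deterministic mutagenesis, and naive
# oracles kept deliberately independent of the package's engines.

ACGT <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

# Deterministic substitution: cycles A->C->G->T->A, so the result is always
# a different base without consuming RNG state.
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[positions] <- nxt[ch[positions]]
  paste(ch, collapse = "")
}

# Naive candidate discovery: explicit per-window loop, no vectorisation,
# used as the enumeration oracle for find_candidate_sites().
naive_discovery <- function(q, cfg) {
  q <- toupper(q)
  L <- cfg$protospacer_length
  W <- L + nchar(cfg$discovery_pam)
  out <- list()
  check <- function(proto, pam, start0, strand) {
    if (grepl("[^ACGT]", proto)) return(NULL)
    pam_ch <- strsplit(pam, "")[[1]]
    motif <- strsplit(cfg$discovery_pam, "")[[1]]
    for (t in seq_along(motif)) {
      if (!iupac_match(motif[t], pam_ch[t])) return(NULL)
    }
    p5 <- cfg$five_prime_constraint
    if (p5 == "GN" && substr(proto, 1, 1) != "G") return(NULL)
    if (p5 == "GG" && substr(proto, 1, 2) != "GG") return(NULL)
    if (cfg$three_prime_constraint == "GG" &&
        substr(proto, L - 1, L) != "GG") return(NULL)
    data.frame(query_start = start0, query_end = start0 + W,
               strand = strand, protospacer = proto, pam = pam,
               stringsAsFactors = FALSE)
  }
  if (nchar(q) >= W) {
    for (i in 1:(nchar(q) - W + 1)) {
      win <- substr(q, i, i + W - 1)
      out[[length(out) + 1]] <-
        check(substr(win, 1, L), substr(win, L + 1, W), i - 1, "+")
      rc <- revcomp(win)
      out[[length(out) + 1]] <-
        check(substr(rc, 1, L), substr(rc, L + 1, W), i - 1, "-")
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(query_start = integer(0), query_end = integer(0),
                      strand = character(0), protospacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$query_start, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# Naive nearest-exon scan over a fixture exon data frame (0-based
# half-open), mirroring the definitions rather than the implementation.
naive_closest <- function(chrom, start0, end0, exons_df, radius = 100000) {
  best <- list(distance = NA_integer_, gene_id = NA_character_)
  if (nrow(exons_df) == 0) return(best)
  cand <- list()
  for (i in seq_len(nrow(exons_df))) {
    e <- exons_df[i, ]
    if (e$chrom != chrom) next
    d <- max(0, start0 - e$end, e$start - end0)
    if (d < radius) {
      cand[[length(cand) + 1]] <- data.frame(d = d, start = e$start,
                                             gene_id = e$gene_id)
    }
  }
  if (length(cand) == 0) return(best)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$start, cand$gene_id), ]
  list(distance = as.integer(cand$d[1]), gene_id = cand$gene_id[1])
}

# Hit tables as order-free comparable keys.
hit_keys <- function(hits) {
  sort(paste(hits$chrom, hits$start, hits$strand, hits$mismatch_positions,
             sep = "/"))
}

# A genome-derived candidate guaranteed to have >= 1 NGG hit: pick a GG
# dinucleotide with enough upstream sequence and mutate the protospacer.
derived_candidate <- function(g, cfg, n_mut_core = 2, n_mut_tail = 2) {
  L <- cfg$protospacer_length
  gg <- gregexpr("GG", g, fixed = TRUE)[[1]]
  gg <- gg[gg >= L + 2]
  if (length(gg) == 0) return(NULL)
  q <- gg[sample.int(length(gg), 1)]       # PAM is (q-1, q, q+1)
  proto <- substr(g, q - 1 - L, q - 2)
  if (grepl("[^ACGT]", proto)) return(NULL)
  core_start <- L - cfg$core_length + 1
  pos <- c(if (n_mut_core > 0) sample(core_start:L, n_mut_core),
           if (n_mut_tail > 0) sample(1:(core_start - 1), n_mut_tail))
  mutate_at(proto, pos)
}
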