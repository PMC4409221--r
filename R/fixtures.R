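# Deterministic synthetic-genome generator with planted on-/off-target
# sites, so every pipeline stage is testable without genome downloads.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe one planted target or off-target site
#'
#' @param base_protospacer The protospacer the plant derives from (pure
#'   ACGT, typically 20 nt).
#' @param mismatch_positions 1-based positions (from the protospacer 5'
#'   end) to mutate; the substituted base is guaranteed to differ from the
#'   original. Planted mutations never touch the PAM.
#' @param pam The 3-nt PAM written next to the plant (e.g. `"TGG"`, or
#'   `"TAG"` for an NRG-only site).
#' @param strand `"+"` or `"-"` (the plant is reverse-complemented into the
#'   forward strand for `"-"`).
#' @param chrom Chromosome name the plant goes into.
#' @param offset 0-based forward-strand offset of the planted window.
#' @param nearest_exon_gap Gap in bases between the plant and a generated
#'   exon (`0` places an overlapping exon; `NA` for no exon).
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(base_protospacer, mismatch_positions = integer(0),
                       pam = "TGG", strand = "+", chrom = "chr1",
                       offset = 0L, nearest_exon_gap = NA_integer_) {
  base_protospacer <- toupper(base_protospacer)
  pam <- toupper(pam)
  stopifnot(.is_acgt(base_protospacer), .is_acgt(pam),
            strand %in% c("+", "-"))
  mismatch_positions <- sort(unique(as.integer(mismatch_positions)))
  if (length(mismatch_positions) > 0 &&
      (min(mismatch_positions) < 1L ||
       max(mismatch_positions) > nchar(base_protospacer))) {
    stop("mismatch positions outside the protospacer")
  }
  structure(list(base_protospacer = base_protospacer,
                 mismatch_positions = mismatch_positions,
                 pam = pam, strand = strand, chrom = chrom,
                 offset = as.integer(offset),
                 nearest_exon_gap = as.integer(nearest_exon_gap)),
            class = "plant_spec")
}

#' Generate a synthetic genome with planted sites and an exon annotation
#'
#' Background sequence is uniform-random ACGT drawn from a private RNG
#' stream seeded with `seed`; generation is bit-reproducible per seed. Each
#' plant is written with exactly the requested substitutions relative to
#' its base protospacer, followed by its PAM (reverse-complemented into the
#' forward strand for `-` plants). Plants overlapping each other raise an
#' error. For each distinct base protospacer the final background is
#' checked with [brute_force_search()] under permissive settings (NRG PAM)
#' and redrawn if random sequence happens to produce a hit away from the
#' planted loci, so the truth table is exhaustive.
#'
#' @param seed Integer seed; part of the fixture's identity.
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bases.
#' @param plants List of [plant_spec()] objects.
#' @param cfg [pattern_config()] used for the background-cleanliness check
#'   and to size windows.
#' @param exon_length Length of each generated exon (default 200).
#' @param max_redraws Background redraw attempts before giving up.
#' @return A list of class `synthetic_fixture` with elements `genome`
#'   (named character vector), `truth` (data.frame: one row per plant with
#'   0-based half-open coordinates, planted sequence, mismatch set) and
#'   `exons` (data.frame convertible via [exons_from_df()]), plus `seed`.
#' @export
make_synthetic_genome <- function(seed, n_chroms = 1L, chrom_length = 50000L,
                                  plants = list(), cfg = pattern_config(),
                                  exon_length = 200L, max_redraws = 20L) {
  stopifnot(inherits(cfg, "pattern_config"))
  n_chroms <- as.integer(n_chroms)
  chrom_length <- as.integer(chrom_length)
  chroms <- paste0("chr", seq_len(n_chroms))
  pam_len <- nchar(cfg$offtarget_pam)
  W <- cfg$protospacer_length + pam_len

  for (p in plants) {
    if (!inherits(p, "plant_spec")) stop("plants must be plant_spec objects")
    if (!(p$chrom %in% chroms)) stop("plant chromosome not in genome: ", p$chrom)
    if (p$offset < 0L || p$offset + W > chrom_length) {
      stop("plant does not fit within its chromosome")
    }
    if (nchar(p$base_protospacer) != cfg$protospacer_length) {
      stop("plant protospacer length does not match configuration")
    }
    if (nchar(p$pam) != pam_len) stop("plant PAM length must be ", pam_len)
  }
  # reject overlapping plants
  if (length(plants) > 1L) {
    key <- vapply(plants, function(p) p$chrom, character(1))
    for (ch in unique(key)) {
      ps <- plants[key == ch]
      iv <- t(vapply(ps, function(p) c(p$offset, p$offset + W), integer(2)))
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
        stop("overlapping plants on ", ch)
      }
    }
  }

  .with_local_seed(seed, {
    # fix the mutated plant sequences once; only background is redrawn
    planted_seqs <- lapply(plants, function(p) {
      bases <- .chars(p$base_protospacer)
      for (pos in p$mismatch_positions) {
        bases[pos] <- sample(setdiff(.ACGT, bases[pos]), 1L)
      }
      proto <- paste(bases, collapse = "")
      site <- paste0(proto, p$pam)
      list(proto = proto,
           forward_insert = if (p$strand == "+") site else revcomp(site))
    })

    check_cfg <- pattern_config(
      protospacer_length = cfg$protospacer_length,
      discovery_pam = cfg$discovery_pam,
      offtarget_pam = "NRG",
      core_length = cfg$core_length,
      max_core_mismatches = cfg$max_core_mismatches,
      max_total_mismatches = cfg$max_total_mismatches,
      exon_assignment_radius = cfg$exon_assignment_radius,
      score_base = cfg$score_base)

    genome <- NULL
    planted_starts <- vapply(plants, function(p) {
      paste0(p$chrom, ":", p$offset)
    }, character(1))
    for (attempt in seq_len(max_redraws)) {
      genome <- vapply(chroms, function(ch) {
        paste(sample(.ACGT, chrom_length, replace = TRUE), collapse = "")
      }, character(1))
      for (i in seq_along(plants)) {
        p <- plants[[i]]
        ins <- planted_seqs[[i]]$forward_insert
        substr(genome[[p$chrom]], p$offset + 1L, p$offset + W) <- ins
      }
      clean <- TRUE
      for (proto in unique(vapply(plants, `[[`, character(1),
                                  "base_protospacer"))) {
        hits <- brute_force_search(proto, genome, check_cfg,
                                   keep_on_target = TRUE)
        extra <- !(paste0(hits$chrom, ":", hits$start) %in% planted_starts)
        if (any(extra)) { clean <- FALSE; break }
      }
      if (clean) break
      if (attempt == max_redraws) {
        stop("could not draw a background free of accidental hits")
      }
    }

    truth <- if (length(plants) == 0L) {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), base_protospacer = character(0),
                 planted_protospacer = character(0), pam = character(0),
                 mismatch_positions = character(0), n_mismatches = integer(0),
                 nearest_exon_gap = integer(0), stringsAsFactors = FALSE)
    } else {
      data.frame(
        chrom = vapply(plants, `[[`, character(1), "chrom"),
        start = vapply(plants, `[[`, integer(1), "offset"),
        end = vapply(plants, function(p) p$offset + W, integer(1)),
        strand = vapply(plants, `[[`, character(1), "strand"),
        base_protospacer = vapply(plants, `[[`, character(1),
                                  "base_protospacer"),
        planted_protospacer = vapply(planted_seqs, `[[`, character(1),
                                     "proto"),
        pam = vapply(plants, `[[`, character(1), "pam"),
        mismatch_positions = vapply(plants, function(p) {
          paste(p$mismatch_positions, collapse = ",")
        }, character(1)),
        n_mismatches = vapply(plants, function(p) {
          length(p$mismatch_positions)
        }, integer(1)),
        nearest_exon_gap = vapply(plants, `[[`, integer(1),
                                  "nearest_exon_gap"),
        stringsAsFactors = FALSE)
    }

    exon_rows <- list()
    for (i in seq_along(plants)) {
      p <- plants[[i]]
      gap <- p$nearest_exon_gap
      if (is.na(gap)) next
      if (gap == 0L) {
        ex_start <- max(0L, p$offset - exon_length %/% 2L)
        ex_end <- ex_start + exon_length
      } else {
        ex_start <- p$offset + W + gap
        ex_end <- ex_start + exon_length
        if (ex_end > chrom_length) {   # place upstream instead
          ex_end <- p$offset - gap
          ex_start <- ex_end - exon_length
          if (ex_start < 0L) stop("exon for plant ", i, " does not fit")
        }
      }
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        chrom = p$chrom, start = ex_start, end = ex_end,
        gene_name = sprintf("gene_%d", i), gene_id = sprintf("GID%03d", i),
        strand = "+", stringsAsFactors = FALSE)
    }
    exons <- if (length(exon_rows) == 0L) {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 gene_name = character(0), gene_id = character(0),
                 strand = character(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, exon_rows)
    }

    structure(list(genome = genome, truth = truth, exons = exons,
                   seed = seed, cfg = cfg),
              class = "synthetic_fixture")
  })
}

#' Rows of a fixture truth table retained under a configuration
#'
#' Recomputes, from the planted sequences alone, which truth-table rows
#' satisfy the off-target constraints of `cfg` for their base protospacer:
#' core mismatches, total mismatches and PAM validity.
#'
#' @param fixture A `synthetic_fixture`.
#' @param cfg A [pattern_config()].
#' @return Logical vector over `fixture$truth` rows.
#' @export
truth_retained <- function(fixture, cfg = fixture$cfg) {
  tt <- fixture$truth
  if (nrow(tt) == 0L) return(logical(0))
  L <- cfg$protospacer_length
  vapply(seq_len(nrow(tt)), function(i) {
    mp <- count_mismatches(tt$base_protospacer[i], tt$planted_protospacer[i])
    length(mp) <= cfg$max_total_mismatches &&
      sum(mp > L - cfg$core_length) <= cfg$max_core_mismatches &&
      .pam_matches(tt$pam[i], cfg$offtarget_pam)
  }, logical(1))
}

#' Write a fixture to disk as FASTA + BED + truth TSV
#'
#' @param fixture A `synthetic_fixture`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             exons = file.path(dir, "exons.bed"),
             truth = file.path(dir, "truth.tsv"))
  set <- Biostrings::DNAStringSet(fixture$genome)
  Biostrings::writeXStringSet(set, paths[["genome"]])
  ex <- fixture$exons
  bed <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                 ex$chrom, ex$start, ex$end, ex$gene_name, ex$gene_id,
                 ex$strand)
  writeLines(bed, paths[["exons"]])
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
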