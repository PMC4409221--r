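# Off-target search: mismatch counting, seed index construction, the
# seed-and-verify engine against the brute-force oracle, planted-site
# truth tables and parameter monotonicity.

cfg_default <- pattern_config()

test_that("count_mismatches reports 1-based positions, ambiguity mismatches", {
  expect_equal(count_mismatches("ACGT", "ACGT"), integer(0))
  expect_equal(count_mismatches("ACGT", "ACGA"), 4L)
  expect_equal(count_mismatches("ACGT", "NCGT"), 1L)
  expect_equal(count_mismatches("ACGT", "acgt"), integer(0))
  expect_equal(count_mismatches("AAAA", "NANA"), c(1L, 3L))
  expect_error(count_mismatches("ACGT", "ACGTA"), "length")
})

test_that("seed index partitions the core by pigeonhole and indexes k-mers", {
  g <- c(chr1 = "ACGTACGTACGT")
  idx <- build_seed_index(g, pattern_config(protospacer_length = 8,
                                            core_length = 12 - 4,
                                            max_core_mismatches = 1))
  expect_equal(idx$segment_sizes, c(4L, 4L))

  idx12 <- build_seed_index(g, pattern_config(core_length = 12,
                                              max_core_mismatches = 2))
  expect_equal(idx12$segment_sizes, c(4L, 4L, 4L))
  idx0 <- build_seed_index(g, pattern_config(core_length = 12,
                                             max_core_mismatches = 0))
  expect_equal(idx0$segment_sizes, 12L)

  # every 4-mer of both strands queryable from the index
  fw <- substring(g[[1]], 1:9, 4:12)
  expect_setequal(index_kmers(idx, 4), unique(c(fw, revcomp(fw))))

  expect_error(build_seed_index(c(chr1 = ""), cfg_default), "empty")
  expect_error(build_seed_index(structure("ACGT", names = NULL),
                                cfg_default), "named")
})

test_that("planted-site truth table: ceilings and PAM modes are honoured", {
  proto <- "GGCGAGGGCGATGCCACCTA"
  plants <- list(
    plant_spec(proto, integer(0), pam = "CGG", chrom = "chr1",
               offset = 1000),                               # on-target
    plant_spec(proto, c(1, 2, 9, 10), pam = "TGG", chrom = "chr1",
               offset = 5000),                               # allowed: 4 total, 2 core
    plant_spec(proto, c(10, 11, 12), pam = "TGG", chrom = "chr1",
               offset = 9000),                               # 3 in 12-bp core: excluded
    plant_spec(proto, c(3, 5), pam = "TAG", strand = "-", chrom = "chr1",
               offset = 12000),                              # NRG-only PAM
    plant_spec(proto, c(1, 2, 3, 4, 5), pam = "TGG", chrom = "chr1",
               offset = 15000))                              # 5 total: excluded
  fx <- make_synthetic_genome(2, 1, 20000, plants, cfg_default)

  hits_ngg <- search_off_targets(proto, fx$genome, cfg_default,
                                 keep_on_target = TRUE)
  tt <- fx$truth
  keep_ngg <- truth_retained(fx, cfg_default)
  expect_equal(hit_keys(hits_ngg),
               sort(paste(tt$chrom, tt$start, tt$strand,
                          tt$mismatch_positions, sep = "/")[keep_ngg]))
  expect_equal(sum(keep_ngg), 2L)      # perfect + {1,2,9,10}

  cfg_nrg <- pattern_config(offtarget_pam = "NRG")
  hits_nrg <- search_off_targets(proto, fx$genome, cfg_nrg,
                                 keep_on_target = TRUE)
  keep_nrg <- truth_retained(fx, cfg_nrg)
  expect_equal(sum(keep_nrg), 3L)      # TAG plant now retained
  expect_equal(hit_keys(hits_nrg),
               sort(paste(tt$chrom, tt$start, tt$strand,
                          tt$mismatch_positions, sep = "/")[keep_nrg]))
  # the NAG/TAG plant appears iff the off-target PAM is NRG
  expect_false("chr1/12000/-/3,5" %in% hit_keys(hits_ngg))
  expect_true("chr1/12000/-/3,5" %in% hit_keys(hits_nrg))

  # every returned hit respects the ceilings and PAM validity
  for (h in list(hits_ngg, hits_nrg)) {
    expect_true(all(h$n_mismatches <= cfg_default$max_total_mismatches))
    expect_true(all(h$n_core_mismatches <= cfg_default$max_core_mismatches))
  }
  expect_true(all(.pam_ok <- vapply(seq_len(nrow(hits_ngg)), function(i) {
    all(iupac_match(strsplit("NGG", "")[[1]],
                    strsplit(hits_ngg$pam_observed[i], "")[[1]]))
  }, logical(1))))
})

test_that("on-target exclusion: lone perfect hit is flagged and dropped", {
  set.seed(31)
  proto <- rand_dna(20)
  g <- c(chr1 = paste0(rand_dna(400), proto, "AGG", rand_dna(400)))
  # guard against accidental matches in this small background
  all_hits <- brute_force_search(proto, g, cfg_default, keep_on_target = TRUE)
  expect_equal(nrow(all_hits), 1L)
  expect_true(all_hits$is_on_target)
  expect_equal(nrow(search_off_targets(proto, g, cfg_default)), 0L)
  expect_equal(nrow(brute_force_search(proto, g, cfg_default)), 0L)

  # an explicit locus overrides the best-hit presumption
  hits <- search_off_targets(proto, g, cfg_default,
                             on_target_locus = list(chrom = "chr1",
                                                    start = 400,
                                                    end = 423))
  expect_equal(nrow(hits), 0L)
  hits2 <- search_off_targets(proto, g, cfg_default,
                              on_target_locus = list(chrom = "chr2",
                                                     start = 0, end = 10))
  expect_equal(nrow(hits2), 1L)       # nothing overlaps: all hits retained

  # a second perfect copy elsewhere stays as an off-target
  g2 <- c(chr1 = paste0(rand_dna(200), proto, "AGG", rand_dna(200),
                        proto, "TGG", rand_dna(200)))
  h <- search_off_targets(proto, g2, cfg_default)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_mismatches, 0L)
})

test_that("seed-and-verify equals brute force on random genomes", {
  set.seed(97)
  for (rep in 1:8) {
    g <- c(chr1 = rand_dna(4000), chr2 = rand_dna(3000))
    for (cfg in list(cfg_default,
                     pattern_config(offtarget_pam = "NRG"),
                     pattern_config(core_length = 10,
                                    max_core_mismatches = 1))) {
      idx <- build_seed_index(g, cfg)
      for (k in 1:3) {
        cand <- derived_candidate(g[[sample(1:2, 1)]], cfg)
        if (is.null(cand)) next
        a <- search_off_targets(cand, idx, cfg, keep_on_target = TRUE)
        b <- brute_force_search(cand, g, cfg, keep_on_target = TRUE)
        expect_identical(a, b)
      }
    }
  }
})

test_that("monotonicity: looser ceilings and PAM only add hits", {
  set.seed(53)
  g <- c(chr1 = rand_dna(8000))
  for (rep in 1:5) {
    cand <- derived_candidate(g[[1]], cfg_default)
    loose <- search_off_targets(cand, g,
                                pattern_config(max_total_mismatches = 4),
                                keep_on_target = TRUE)
    tight <- search_off_targets(cand, g,
                                pattern_config(max_total_mismatches = 3,
                                               max_core_mismatches = 2),
                                keep_on_target = TRUE)
    expect_true(all(hit_keys(tight) %in% hit_keys(loose)))
    ngg <- search_off_targets(cand, g, cfg_default, keep_on_target = TRUE)
    nrg <- search_off_targets(cand, g, pattern_config(offtarget_pam = "NRG"),
                              keep_on_target = TRUE)
    expect_true(all(hit_keys(ngg) %in% hit_keys(nrg)))
  }
})

test_that("windows never cross chromosome boundaries", {
  proto <- "GGCGAGGGCGATGCCACCTA"
  # the site split across two records must not be reported
  g <- c(chr1 = paste0(strrep("T", 50), substr(proto, 1, 10)),
         chr2 = paste0(substr(proto, 11, 20), "AGG", strrep("T", 50)))
  expect_equal(nrow(search_off_targets(proto, g, cfg_default,
                                       keep_on_target = TRUE)), 0L)
  # flush against the end of a record is fine
  g2 <- c(chr1 = paste0(strrep("T", 50), proto, "AGG"))
  h <- search_off_targets(proto, g2, cfg_default, keep_on_target = TRUE)
  expect_equal(h$start, 50L)
})

test_that("candidate validation rejects impure or mis-sized protospacers", {
  g <- c(chr1 = strrep("ACGT", 100))
  expect_error(search_off_targets("ACGTNACGTACGTACGTACG", g, cfg_default),
               "ACGT")
  expect_error(search_off_targets("ACGT", g, cfg_default), "length")
})
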