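# Pipeline orchestration, report writers and the CLI layer.

cfg_default <- pattern_config()
PROTO <- "GGCGAGGGCGATGCCACCTA"

make_run_fixture <- function(seed = 2) {
  plants <- list(
    plant_spec(PROTO, integer(0), pam = "CGG", offset = 1000),
    plant_spec(PROTO, c(1, 2, 9, 10), pam = "TGG", offset = 5000,
               nearest_exon_gap = 300L),
    plant_spec(PROTO, c(10, 11, 12), pam = "TGG", offset = 9000),
    plant_spec(PROTO, c(3, 5), pam = "TAG", strand = "-", offset = 12000))
  make_synthetic_genome(seed, 1, 20000, plants, cfg_default)
}

# query around the on-target plant, GG-constrained so only that candidate
# survives discovery
run_query <- function(fx) substr(fx$genome[["chr1"]], 951, 1073)

test_that("run_pipeline recovers the fixture truth end-to-end", {
  fx <- make_run_fixture()
  cfg <- pattern_config(five_prime_constraint = "GG",
                        three_prime_constraint = "NN")
  report <- run_pipeline(run_query(fx), fx$genome, fx$exons, cfg)
  sites <- report$sites
  main <- sites[sites$protospacer == PROTO, ]
  expect_equal(nrow(main), 1L)
  # on-target locus is the perfect plant
  expect_equal(main$on_start, 1000L)
  off <- report$off_targets[[main$site_id]]
  # retained truth minus the on-target = the single 4-mismatch plant
  expect_equal(off$start, 5000L)
  expect_equal(off$distance, 300L)
  expect_equal(off$mismatch_score,
               off_target_score(c(1, 2, 9, 10)), tolerance = 1e-12)
  expect_equal(main$rank_score,
               log10(300) + off_target_score(c(1, 2, 9, 10)) - 1,
               tolerance = 1e-12)
  expect_equal(main$total_off_targets, 1L)
})

test_that("zero-candidate queries give an empty, writable report", {
  fx <- make_run_fixture()
  report <- run_pipeline(strrep("A", 30), fx$genome, fx$exons, cfg_default)
  expect_equal(nrow(report$sites), 0L)
  dir <- withr::local_tempdir()
  expect_warning(write_candidates_fasta(report, file.path(dir, "c.fa")),
                 "empty")
  expect_true(file.exists(file.path(dir, "c.fa")))
})

test_that("missing inputs produce stage-tagged errors", {
  fx <- make_run_fixture()
  expect_error(run_pipeline(run_query(fx), "/nonexistent/genome.fa",
                            NULL, cfg_default), "seed index")
  expect_error(run_pipeline(run_query(fx), fx$genome,
                            "/nonexistent/exons.bed", cfg_default),
               "exon annotation")
})

test_that("candidates FASTA round-trips and headers carry rank/coords", {
  fx <- make_run_fixture()
  report <- run_pipeline(run_query(fx), fx$genome, fx$exons, cfg_default)
  path <- withr::local_tempfile(fileext = ".fa")
  write_candidates_fasta(report, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), nrow(report$sites))
  expect_identical(as.character(back, use.names = FALSE),
                   paste0(report$sites$protospacer, report$sites$pam))
  expect_identical(names(back),
                   sprintf("%s|%d-%d|%s", report$sites$site_id,
                           report$sites$query_start + 1L,
                           report$sites$query_end, report$sites$strand))
})

test_that("TSV layout: constant columns, 4-decimal scores, lowercased
           mismatches, 1-based coordinates", {
  fx <- make_run_fixture()
  cfg <- pattern_config(five_prime_constraint = "GG")
  report <- run_pipeline(run_query(fx), fx$genome, fx$exons, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_full_tsv(report, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  ncols <- lengths(strsplit(body, "\t", fixed = TRUE))
  expect_true(all(ncols == ncols[1]))

  site_rows <- body[startsWith(body, "site\t")]
  expect_equal(length(site_rows), nrow(report$sites))
  off_rows <- strsplit(body[startsWith(body, "offtarget\t")], "\t")[[1]]
  # 1-based genomic start of the 4-mismatch plant
  expect_equal(off_rows[4], "5001")
  # mismatched bases lowercased at the planted positions
  seq_rendered <- off_rows[7]
  expect_equal(which(strsplit(seq_rendered, "")[[1]] %in%
                       c("a", "c", "g", "t")), c(1L, 2L, 9L, 10L))
  # scores rendered with 4 decimals
  expect_match(off_rows[9], "^-?[0-9]+\\.[0-9]{4}$")
})

test_that("BED track rescales scores to 0-1000 and round-trips intervals", {
  fx <- make_run_fixture()
  cfg <- pattern_config(five_prime_constraint = "GG")
  report <- run_pipeline(run_query(fx), fx$genome, fx$exons, cfg)
  path <- withr::local_tempfile(fileext = ".bed")

  # single located site: degenerate rescale maps to 1000
  fake1 <- report
  fake1$sites <- report$sites[1, , drop = FALSE]
  write_track_bed(fake1, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(nrow(bed), 1L)
  expect_equal(bed$V5, 1000L)
  expect_equal(bed$V2, fake1$sites$on_start[1])
  expect_equal(bed$V3, fake1$sites$on_end[1])

  # synthetic two-site report: min-max endpoints map to 0 and 1000
  fake <- report
  fake$sites <- rbind(report$sites[1, ], report$sites[1, ])
  fake$sites$site_id <- c("T1", "T2")
  fake$sites$rank_score <- c(10, 0)
  write_track_bed(fake, path)
  bed2 <- utils::read.table(path, sep = "\t")
  expect_equal(bed2$V5, c(1000L, 0L))

  # sites without a locus are skipped with a warning
  fake$sites$on_chrom[2] <- NA
  expect_warning(write_track_bed(fake, path), "skipped")
  expect_equal(nrow(utils::read.table(path, sep = "\t")), 1L)
})

test_that("identical inputs produce byte-identical outputs", {
  fx <- make_run_fixture()
  dirs <- c(withr::local_tempdir(), withr::local_tempdir())
  for (d in dirs) {
    run_pipeline(run_query(fx), fx$genome, fx$exons, cfg_default,
                 output_dir = d)
  }
  for (f in c("candidates.fasta", "results.tsv", "track.bed")) {
    a <- file.path(dirs[1], f)
    b <- file.path(dirs[2], f)
    expect_true(file.exists(a))
    expect_identical(readLines(a), readLines(b))
  }
})

test_that("the CLI subcommands drive the same pipeline", {
  skip_if_not_installed("optparse")
  fx <- make_run_fixture()
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  qfa <- file.path(dir, "query.fa")
  writeLines(c(">q", run_query(fx)), qfa)

  out <- file.path(dir, "sites.tsv")
  cli_main(c("discover", "--query", qfa, "--out", out,
             "--pam", "N20NGG"))
  sites <- utils::read.table(out, header = TRUE, sep = "\t")
  expect_true(PROTO %in% sites$protospacer)

  out2 <- file.path(dir, "hits.tsv")
  cli_main(c("search", "--protospacer", PROTO, "--genome",
             paths[["genome"]], "--ot-pam", "NRG", "--out", out2))
  hits <- utils::read.table(out2, header = TRUE, sep = "\t")
  expect_equal(sort(hits$start), sort(fx$truth$start[truth_retained(
    fx, pattern_config(offtarget_pam = "NRG"))]))

  outdir <- file.path(dir, "run")
  invisible(utils::capture.output(suppressMessages(
    cli_main(c("run", "--query", qfa, "--genome", paths[["genome"]],
               "--exon-bed", paths[["exons"]], "--out-dir", outdir)))))
  expect_true(file.exists(file.path(outdir, "results.tsv")))
})
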