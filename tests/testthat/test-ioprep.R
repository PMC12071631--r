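test_that("primer matching trims both primers and orients reads", {
  cfg <- test_amplicon()
  insert <- "ACGTACGTACGTACGTACGTACGT"
  molecule <- paste0(PRIMER_F, insert, revcomp_dna(PRIMER_R))
  qual <- seq_len(nchar(molecule))

  m <- match_and_trim_primers(molecule, qual, cfg)
  expect_identical(m$seq, insert)
  expect_false(m$flipped)
  expect_identical(m$qual, qual[(nchar(PRIMER_F) + 1):(nchar(PRIMER_F) + nchar(insert))])

  # same read on the minus strand: identical insert, flipped = TRUE
  m2 <- match_and_trim_primers(revcomp_dna(molecule), rev(qual), cfg)
  expect_identical(m2$seq, insert)
  expect_true(m2$flipped)
  expect_identical(m2$qual, m$qual)

  # missing reverse primer is a rejection
  expect_null(match_and_trim_primers(
    paste0(PRIMER_F, insert), rep(30L, nchar(PRIMER_F) + nchar(insert)), cfg
  ))
  # missing forward primer likewise
  expect_null(match_and_trim_primers(
    paste0(insert, revcomp_dna(PRIMER_R)),
    rep(30L, nchar(insert) + nchar(PRIMER_R)), cfg
  ))
})

test_that("primer matching honours IUPAC degeneracy and the error tolerance", {
  cfg <- amplicon_config("ACGWTTAGCCGTAGGCN", PRIMER_R,
                         min_len = 10, max_len = 200)
  insert <- "TTTTGGGGCCCCAAAATTTTGGGG"
  # W matched by T, N matched by anything
  molecule <- paste0("ACGTTTAGCCGTAGGCG", insert, revcomp_dna(PRIMER_R))
  m <- match_and_trim_primers(molecule, rep(30L, nchar(molecule)), cfg)
  expect_identical(m$seq, insert)

  # one mismatch within floor(0.1 * 17) = 1 is tolerated
  cfg2 <- test_amplicon()
  mut_f <- sub("^A", "T", PRIMER_F)
  mol2 <- paste0(mut_f, insert, revcomp_dna(PRIMER_R))
  m2 <- match_and_trim_primers(mol2, rep(30L, nchar(mol2)), cfg2)
  expect_identical(m2$seq, insert)

  # three mismatches exceed the tolerance
  mut_f3 <- paste0("TTT", substr(PRIMER_F, 4, nchar(PRIMER_F)))
  mol3 <- paste0(mut_f3, insert, revcomp_dna(PRIMER_R))
  expect_null(match_and_trim_primers(mol3, rep(30L, nchar(mol3)), cfg2))
})

test_that("reads and their reverse complements yield identical prepared reads", {
  cfg <- test_amplicon()
  set.seed(71)
  for (i in 1:10) {
    insert <- random_dna(sample(50:200, 1))
    mol <- paste0(PRIMER_F, insert, revcomp_dna(PRIMER_R))
    qual <- sample(5:45, nchar(mol), replace = TRUE)
    a <- match_and_trim_primers(mol, qual, cfg)
    b <- match_and_trim_primers(revcomp_dna(mol), rev(qual), cfg)
    expect_identical(a$seq, insert)
    expect_identical(a$seq, b$seq)
    expect_identical(a$qual, b$qual)
    # orientation idempotence: re-decorating the trimmed insert reproduces it
    c <- match_and_trim_primers(
      paste0(PRIMER_F, a$seq, revcomp_dna(PRIMER_R)),
      c(rep(30L, nchar(PRIMER_F)), a$qual, rep(30L, nchar(PRIMER_R))), cfg
    )
    expect_identical(c$seq, insert)
  }
})

test_that("median quality excludes cap-artifact positions", {
  expect_equal(median_quality(c(20, 20, 20)), 20)
  expect_equal(median_quality(c(10, 20, 30, 90, 90)), 20)
  # all positions capped: fall back to the full-vector median
  expect_equal(median_quality(c(90, 90)), 90)
  expect_equal(median_quality(c(15, 25), q_cap_exclude = 90), 20)
})

test_that("length and quality filters follow the configured amplicon bounds", {
  mk <- function(len, q) .read_set("r", random_dna(len), list(rep(q, len)), "s")
  v1v9 <- amplicon_presets$v1v9
  expect_equal(v1v9$min_len, 900L)
  expect_equal(v1v9$max_len, 1600L)

  set.seed(3)
  out <- filter_reads(mk(800, 30L), v1v9)
  expect_equal(out$log[["too_short"]], 1L)
  expect_equal(nrow(out$kept), 0L)

  out <- filter_reads(mk(1700, 30L), v1v9)
  expect_equal(out$log[["too_long"]], 1L)

  its1 <- amplicon_presets$its1
  out <- filter_reads(mk(300, 25L), its1)
  expect_equal(out$log[["kept"]], 1L)
  expect_equal(nrow(out$kept), 1L)

  out <- filter_reads(mk(300, 15L), its1)
  expect_equal(out$log[["bad_quality"]], 1L)

  # Q20 is inclusive
  out <- filter_reads(mk(300, 20L), its1)
  expect_equal(out$log[["kept"]], 1L)

  # empty input: zeroed log, no error
  empty <- data.frame(id = character(0), seq = character(0),
                      sample_id = character(0), flipped = logical(0))
  empty$qual <- list()
  out <- filter_reads(empty, its1)
  expect_equal(sum(out$log), 0L)
})

test_that("attrition log conserves every input read once", {
  cfg <- test_amplicon(min_len = 150, max_len = 400)
  set.seed(9)
  tpls <- make_templates(2, c(250, 900)) # second template violates max_len
  spec <- noisy_spec(tpls, c(0.6, 0.4), n_reads = 60, seed = 4)
  d <- simulate_dataset(spec)
  prep <- prepare_sample(d$samples$S1, cfg)
  expect_equal(sum(prep$log), 60L)
  expect_equal(prep$log[["kept"]], nrow(prep$reads))
  expect_gt(prep$log[["too_long"]], 0L)
  # prepared reads carry co-trimmed qualities
  expect_true(all(nchar(prep$reads$seq) == lengths(prep$reads$qual)))
})

test_that("FASTQ round trip preserves reads, qualities and gzip works", {
  set.seed(12)
  tpl <- make_templates(1, 200)
  d <- simulate_dataset(clean_spec(tpl, n_reads = 8, seed = 2))
  for (ext in c(".fastq", ".fastq.gz")) {
    f <- tempfile(fileext = ext)
    write_fastq(d$samples$S1, f)
    back <- read_fastq(f, sample_id = "S1")
    expect_identical(back$seq, d$samples$S1$seq)
    expect_identical(back$qual, d$samples$S1$qual)
    expect_identical(back$id, d$samples$S1$id)
    unlink(f)
  }
})
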