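# Build a cluster_msa by hand from gapped rows and per-column qualities
# (NA at gaps), bypassing the aligner.
.msa <- function(rows, quals) {
  aln <- do.call(rbind, strsplit(rows, ""))
  qmat <- do.call(rbind, quals)
  stopifnot(all(is.na(qmat[aln == "-"])))
  structure(list(aln = aln, qual = qmat, ids = paste0("r", seq_along(rows))),
            class = "cluster_msa")
}

test_that("alignment reproduces each read after degapping (both backends)", {
  set.seed(61)
  tpl <- random_dna(300)
  spec <- noisy_spec(setNames(tpl, "t"), n_reads = 12, seed = 9,
                     flip_prob = 0)
  d <- simulate_dataset(spec)
  r <- d$samples$S1
  for (method in c("mafft", "centerstar")) {
    if (method == "mafft" && !nzchar(Sys.which("mafft"))) next
    msa <- align_cluster(r$seq, r$qual, r$id, method = method)
    L <- ncol(msa$aln)
    for (i in seq_len(nrow(msa$aln))) {
      row <- msa$aln[i, ]
      expect_identical(paste(row[row != "-"], collapse = ""), r$seq[[i]])
      # qualities carried to aligned coordinates
      expect_identical(msa$qual[i, row != "-"], r$qual[[i]])
      expect_true(all(is.na(msa$qual[i, row == "-"])))
    }
  }
})

test_that("a deletion in one read produces a gap column", {
  msa <- align_cluster(c("ACGT", "AGT", "ACGT"),
                       flat_qual(c("ACGT", "AGT", "ACGT")),
                       method = "centerstar")
  expect_equal(ncol(msa$aln), 4)
  expect_identical(unname(msa$aln[2, 2]), "-")
})

test_that("proto-consensus rules cover all four branches", {
  # unanimous letter
  expect_identical(call_proto_consensus(.msa(
    rep("A", 5), replicate(5, 20L, simplify = FALSE)
  )), "A")

  # gap plurality: 4 gaps vs 3 letters -> "-"
  expect_identical(call_proto_consensus(.msa(
    c(rep("-", 4), rep("A", 3)),
    c(replicate(4, NA_integer_, simplify = FALSE),
      replicate(3, 20L, simplify = FALSE))
  )), "-")

  # gap/letter tie goes to the letter
  expect_identical(call_proto_consensus(.msa(
    c(rep("-", 3), rep("A", 3)),
    c(replicate(3, NA_integer_, simplify = FALSE),
      replicate(3, 20L, simplify = FALSE))
  )), "A")

  # frequency/quality conflict -> N: A x4 at Q12 vs G x3 at Q30
  expect_identical(call_proto_consensus(.msa(
    c(rep("A", 4), rep("G", 3)),
    c(replicate(4, 12L, simplify = FALSE),
      replicate(3, 30L, simplify = FALSE))
  )), "N")

  # insufficient support -> N: A x2 + C x1, all at Q40
  expect_identical(call_proto_consensus(.msa(
    c("A", "A", "C"), list(40L, 40L, 40L)
  )), "N")

  # quality winner among supported letters when counts tie
  expect_identical(call_proto_consensus(.msa(
    c(rep("A", 3), rep("G", 3)),
    c(replicate(3, 12L, simplify = FALSE),
      replicate(3, 30L, simplify = FALSE))
  )), "G")

  # Q90 cap positions carry no confidence: a capped minority letter does
  # not overturn the majority
  expect_identical(call_proto_consensus(.msa(
    c(rep("A", 8), rep("G", 3)),
    c(replicate(8, 25L, simplify = FALSE), list(90L, 90L, 90L))
  )), "A")
})

test_that("proto-consensus is invariant to row permutation", {
  set.seed(77)
  rows <- c("ACGT", "AC-T", "ACGT", "AGGT", "ACGT")
  quals <- list(c(20L, 25L, 30L, 35L), c(22L, 21L, NA, 33L),
                c(18L, 28L, 31L, 30L), c(25L, 24L, 12L, 29L),
                c(30L, 26L, 29L, 28L))
  base <- call_proto_consensus(.msa(rows, quals))
  for (i in 1:5) {
    p <- sample(5)
    expect_identical(call_proto_consensus(.msa(rows[p], quals[p])), base)
  }
})

test_that("gap stripping and poly-N trimming behave on edge cases", {
  expect_identical(strip_gaps("AC-G-"), "ACG")
  expect_identical(strip_gaps("---"), "")
  expect_identical(strip_gaps("ACGT"), "ACGT")
  expect_identical(trim_polyN("NNNACGTNN"), "ACGT")
  expect_identical(trim_polyN("ACNGT"), "ACNGT")
  expect_identical(trim_polyN("NNNN"), "")
})

test_that("identical error-free reads reproduce their sequence exactly", {
  set.seed(81)
  tpl <- random_dna(200)
  cons <- build_consensus(rep(tpl, 4), flat_qual(rep(tpl, 4)))
  expect_identical(cons$final_seq, tpl)
  expect_equal(cons$support, 4)
  expect_false(cons$polished)
})

test_that("noisy clusters assemble to >= 99% identity at 5% error", {
  set.seed(91)
  tpl <- make_templates(1, 500)
  spec <- noisy_spec(tpl, n_reads = 100, seed = 14,
                     sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.02)
  d <- simulate_dataset(spec)
  r <- prepare_sample(d$samples$S1, test_amplicon())$reads
  expect_gte(nrow(r), 10)
  cons <- build_consensus(r$seq, r$qual, r$id)
  expect_gte(pct_identity(cons$final_seq, tpl[[1]]), 99)
  expect_equal(cons$support, nrow(r))
})

test_that("polishing passes through unchanged when medaka is absent", {
  has_medaka <- nzchar(Sys.which("medaka_consensus"))
  tpl <- random_dna(100, seed = 31)
  cons <- build_consensus(rep(tpl, 3), flat_qual(rep(tpl, 3)))
  if (has_medaka) {
    polished <- polish_consensus(cons, rep(tpl, 3), flat_qual(rep(tpl, 3)))
    # a correct consensus must not get worse
    expect_gte(pct_identity(polished$final_seq, tpl), 100)
  } else {
    expect_warning(
      polished <- polish_consensus(cons, rep(tpl, 3), flat_qual(rep(tpl, 3))),
      "unpolished"
    )
    expect_identical(polished$final_seq, cons$final_seq)
    expect_false(polished$polished)
  }
})
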