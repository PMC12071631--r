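#' Generate divergent template sequences
#'
#' Random DNA templates for simulated amplicon communities. Independent
#' uniform-random sequences share only ~25% background identity, far below
#' any clustering threshold, so each template behaves as a distinct
#' amplicon variant. Sequences are generated with the current RNG state.
#'
#' @param n number of templates.
#' @param length_bp template length in bp (recycled over templates).
#' @param gc target GC content (default 0.5).
#' @param prefix template name prefix.
#' @return named character vector of DNA sequences.
#' @export
make_templates <- function(n, length_bp, gc = 0.5, prefix = "template") {
  length_bp <- rep_len(length_bp, n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(names(p), length_bp[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1L))
  names(out) <- paste0(prefix, seq_len(n))
  out
}

#' Specify a simulated amplicon community
#'
#' Defines the templates, their proportions, the per-read error and
#' quality models, and the primer decoration used by
#' [simulate_dataset()]. Defaults emulate Guppy-era nanopore amplicon
#' reads: ~8% total error dominated by indels, indel rates inflated inside
#' homopolymer runs, mid-20s base qualities with occasional positions
#' pinned at Q90 (a basecaller floating-point cap artifact), and random
#' read orientation.
#'
#' @param templates named character vector of template sequences.
#' @param proportions template proportions, summing to 1.
#' @param n_reads reads per sample.
#' @param samples character vector of sample ids (default `"S1"`).
#' @param sub_rate,ins_rate,del_rate per-base substitution / insertion /
#'   deletion probabilities (defaults 0.03 / 0.02 / 0.03).
#' @param hp_multiplier multiplier on indel rates inside homopolymer runs
#'   of length >= 3 (default 2).
#' @param mean_q,sd_q Phred quality model for correctly called bases
#'   (default 25 +/- 6).
#' @param err_q_mean,err_q_sd quality model for erroneous bases (default
#'   12 +/- 4): basecaller confidence is lower where it errs.
#' @param q90_prob probability a position is pinned to Q90 (default 0.01).
#' @param primer_f,primer_r primers decorating each read (IUPAC codes are
#'   instantiated randomly per read); defaults are the 16S V3--V4 pair.
#' @param flip_prob probability a read is emitted reverse-complemented
#'   (default 0.5).
#' @param seed RNG seed used by [simulate_dataset()] (default 42).
#' @return a `community_spec` list.
#' @export
community_spec <- function(templates, proportions, n_reads,
                           samples = "S1",
                           sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03,
                           hp_multiplier = 2,
                           mean_q = 25, sd_q = 6,
                           err_q_mean = 12, err_q_sd = 4,
                           q90_prob = 0.01,
                           primer_f = "CCTACGGGNGGCWGCAG",
                           primer_r = "GACTACHVGGGTATCTAATCC",
                           flip_prob = 0.5, seed = 42L) {
  stopifnot(
    length(templates) == length(proportions),
    abs(sum(proportions) - 1) < 1e-9,
    all(c(sub_rate, ins_rate, del_rate) >= 0),
    all(c(sub_rate, ins_rate, del_rate) < 1),
    !is.null(names(templates))
  )
  structure(
    list(
      templates = templates, proportions = proportions,
      n_reads = as.integer(n_reads), samples = samples,
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      hp_multiplier = hp_multiplier,
      mean_q = mean_q, sd_q = sd_q,
      err_q_mean = err_q_mean, err_q_sd = err_q_sd,
      q90_prob = q90_prob,
      primer_f = toupper(primer_f), primer_r = toupper(primer_r),
      flip_prob = flip_prob, seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

# Per-position homopolymer-run lengths of a sequence.
.run_lengths_by_pos <- function(chars) {
  r <- rle(chars)
  rep(r$lengths, r$lengths)
}

# Mutate a molecule under the spec's error model. Returns the read
# characters, a parallel logical marking erroneous characters (substituted
# or inserted), and the edit counts.
.mutate_molecule <- function(chars, spec) {
  n <- length(chars)
  hp <- .run_lengths_by_pos(chars) >= 3L
  mult <- ifelse(hp, spec$hp_multiplier, 1)
  del_p <- pmin(spec$del_rate * mult, 0.95)
  ins_p <- pmin(spec$ins_rate * mult, 0.95)
  del <- runif(n) < del_p
  sub <- !del & runif(n) < spec$sub_rate
  ins <- runif(n) < ins_p
  base_out <- chars
  if (any(sub)) {
    base_out[sub] <- vapply(chars[sub], function(b) {
      alt <- setdiff(c("A", "C", "G", "T"), b)
      alt[sample.int(3L, 1L)]
    }, character(1L))
  }
  n_ins <- sum(ins)
  ins_bases <- if (n_ins > 0L) {
    c("A", "C", "G", "T")[sample.int(4L, n_ins, replace = TRUE)]
  } else character(0)
  keep <- !del
  # bases flanking a deletion: the basecaller is locally uncertain where it
  # drops a base, so these draw from the error-quality model too
  adj_del <- (c(FALSE, del[-n]) | c(del[-1L], FALSE)) & keep
  keys <- c(seq_len(n)[keep], seq_len(n)[ins] + 0.5)
  out <- c(base_out[keep], ins_bases)
  err <- c(sub[keep] | adj_del[keep], rep(TRUE, n_ins))
  o <- order(keys)
  list(
    chars = out[o], err = err[o],
    n_sub = sum(sub), n_ins = n_ins, n_del = sum(del)
  )
}

#' Simulate one nanopore amplicon read
#'
#' Builds the molecule `primer_f + template + revcomp(primer_r)` (IUPAC
#' primer positions instantiated randomly), applies the error model over
#' the whole molecule, draws per-base qualities (erroneous bases from the
#' low-quality model, a `q90_prob` fraction pinned at Q90) and flips the
#' read to the minus strand with probability `flip_prob`. Uses the current
#' RNG state; [simulate_dataset()] seeds it.
#'
#' @param template template DNA string.
#' @param spec a [community_spec()].
#' @param id read identifier; edit counts are appended to it so realized
#'   error rates can be audited from the read id alone.
#' @return a list: `id`, `seq`, `qual`, `flipped`, `n_sub`, `n_ins`,
#'   `n_del`.
#' @export
simulate_read <- function(template, spec, id = "read") {
  molecule <- paste0(
    .instantiate_iupac(spec$primer_f),
    template,
    revcomp_dna(.instantiate_iupac(spec$primer_r))
  )
  chars <- strsplit(molecule, "", fixed = TRUE)[[1L]]
  mut <- .mutate_molecule(chars, spec)
  len <- length(mut$chars)
  qual <- as.integer(round(rnorm(len, spec$mean_q, spec$sd_q)))
  n_err <- sum(mut$err)
  if (n_err > 0L) {
    qual[mut$err] <- as.integer(round(rnorm(n_err, spec$err_q_mean,
                                            spec$err_q_sd)))
  }
  qual <- pmax(pmin(qual, 60L), 1L)
  if (spec$q90_prob > 0) {
    qual[runif(len) < spec$q90_prob] <- 90L
  }
  seq <- paste(mut$chars, collapse = "")
  flipped <- runif(1L) < spec$flip_prob
  if (flipped) {
    seq <- revcomp_dna(seq)
    qual <- rev(qual)
  }
  list(
    id = sprintf("%s;sub=%d;ins=%d;del=%d", id, mut$n_sub, mut$n_ins,
                 mut$n_del),
    seq = seq, qual = qual, flipped = flipped,
    n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del
  )
}

#' Simulate a multi-sample amplicon dataset with known ground truth
#'
#' For each sample, template assignments are drawn multinomially from the
#' community proportions and each read is simulated with
#' [simulate_read()]. A fixed `spec$seed` makes the whole dataset
#' reproducible byte-for-byte.
#'
#' @param spec a [community_spec()].
#' @param dir optional output directory; when given, one
#'   `<sample>.fastq.gz` per sample plus `truth.tsv` and
#'   `templates.fasta` are written there.
#' @return list with `samples` (named list of read-set data frames),
#'   `truth` (data frame `read_id`, `sample_id`, `template`), and `paths`
#'   (named FASTQ paths, when `dir` was given).
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  tnames <- names(spec$templates)
  samples <- list()
  truth <- list()
  for (s in spec$samples) {
    assign <- sample(tnames, spec$n_reads, replace = TRUE,
                     prob = spec$proportions)
    reads <- lapply(seq_len(spec$n_reads), function(i) {
      simulate_read(
        spec$templates[[assign[i]]], spec,
        id = sprintf("%s_r%05d;tmpl=%s", s, i, assign[i])
      )
    })
    samples[[s]] <- .read_set(
      id = vapply(reads, `[[`, character(1L), "id"),
      seq = vapply(reads, `[[`, character(1L), "seq"),
      qual = lapply(reads, `[[`, "qual"),
      sample_id = s
    )
    truth[[s]] <- data.frame(
      read_id = samples[[s]]$id,
      sample_id = s,
      template = assign,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- setNames(
      file.path(dir, paste0(spec$samples, ".fastq.gz")), spec$samples
    )
    for (s in spec$samples) write_fastq(samples[[s]], paths[[s]])
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeLines(
      as.vector(rbind(paste0(">", tnames), unname(spec$templates))),
      file.path(dir, "templates.fasta")
    )
  }
  list(samples = samples, truth = truth, paths = paths)
}
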