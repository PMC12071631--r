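# Shared fixtures, all generated in code.

# Concrete (IUPAC-free) primer pair: lets tests assert byte-exact
# decoration round trips.
PRIMER_F <- "ACGGTTAGCCGTAGGCA"
PRIMER_R <- "TTGCACGGAACCTGTGA"

test_amplicon <- function(min_len = 100, max_len = 1600, ...) {
  amplicon_config(PRIMER_F, PRIMER_R, min_len = min_len, max_len = max_len,
                  ...)
}

# Error-free community spec (no flips, no Q90) for exactness tests.
clean_spec <- function(templates, proportions = NULL, n_reads = 10,
                       seed = 1L, ...) {
  community_spec(
    templates,
    proportions %||% rep(1 / length(templates), length(templates)),
    n_reads = n_reads,
    sub_rate = 0, ins_rate = 0, del_rate = 0, q90_prob = 0,
    flip_prob = 0, primer_f = PRIMER_F, primer_r = PRIMER_R,
    seed = seed, ...
  )
}

# Default (noisy) spec bound to the concrete primers.
noisy_spec <- function(templates, proportions = NULL, n_reads = 100,
                       seed = 1L, ...) {
  community_spec(
    templates,
    proportions %||% rep(1 / length(templates), length(templates)),
    n_reads = n_reads,
    primer_f = PRIMER_F, primer_r = PRIMER_R,
    seed = seed, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Percent identity of a sequence to a template by global alignment.
pct_identity <- function(seq, template) {
  Biostrings::pid(Biostrings::pairwiseAlignment(seq, template,
                                                type = "global"))
}

# Constant-quality helper for constructing reads by hand.
flat_qual <- function(seqs, q = 30L) lapply(nchar(seqs), function(n) rep(q, n))
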