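#' Amplicon configuration
#'
#' Bundles the primer pair, expected amplicon length bounds and quality
#' thresholds that drive read preparation.
#'
#' @param primer_f,primer_r forward and reverse primer sequences, written
#'   5'->3' on their respective strands; IUPAC ambiguity codes allowed.
#' @param min_len,max_len expected amplicon length bounds in bp (insert
#'   length after primer removal).
#' @param q_min minimum median Phred quality of a read (default 20,
#'   inclusive).
#' @param q_cap_exclude Phred value marking the basecaller's numeric-cap
#'   artifact; positions at or above it are excluded from the median
#'   quality (default 90).
#' @param primer_error_rate tolerated primer mismatch+indel rate, as a
#'   fraction of primer length (default 0.1).
#' @return an `amplicon_config` list.
#' @seealso [amplicon_presets] for ready-made marker-gene configurations.
#' @export
amplicon_config <- function(primer_f, primer_r, min_len, max_len,
                            q_min = 20, q_cap_exclude = 90L,
                            primer_error_rate = 0.1) {
  stopifnot(
    nzchar(primer_f), nzchar(primer_r),
    min_len > 0, min_len <= max_len,
    primer_error_rate >= 0, primer_error_rate < 1
  )
  structure(
    list(
      primer_f = toupper(primer_f), primer_r = toupper(primer_r),
      min_len = as.integer(min_len), max_len = as.integer(max_len),
      q_min = q_min, q_cap_exclude = as.integer(q_cap_exclude),
      primer_error_rate = primer_error_rate
    ),
    class = "amplicon_config"
  )
}

#' Marker-gene amplicon presets
#'
#' Standard primer pairs and expected insert length bounds for the common
#' 16S rRNA and fungal ITS amplicons: 341F/805R for 16S V3--V4, 27F/1492R
#' for 16S V1--V9, and the usual ITS1 / ITS2 / full-ITS primer pairs.
#'
#' @format a named list of [amplicon_config()] objects with entries
#'   `v3v4`, `v1v9`, `its1`, `its2`, `its_full`.
#' @export
amplicon_presets <- list(
  v3v4 = amplicon_config("CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC",
                         min_len = 350, max_len = 600),
  v1v9 = amplicon_config("AGRGTTYGATYMTGGCTCAG", "CGGYTACCTTGTTACGACTT",
                         min_len = 900, max_len = 1600),
  its1 = amplicon_config("GGAAGTAAAAGTCGTAACAAGG", "GCTGCGTTCTTCATCGATGC",
                         min_len = 100, max_len = 500),
  its2 = amplicon_config("GCATCGATGAAGAACGCAGC", "TCCTCCGCTTATTGATATGC",
                         min_len = 100, max_len = 500),
  its_full = amplicon_config("GGAAGTAAAAGTCGTAACAAGG", "TCCTCCGCTTATTGATATGC",
                             min_len = 300, max_len = 1200)
)

# Locate primer_f near the 5' end and revcomp(primer_r) near the 3' end of
# `subject` (plus orientation assumed). Approximate matching allows
# mismatches and indels up to floor(error_rate * primer length); IUPAC
# degeneracy in the primer matches any compatible subject base.
.locate_primers <- function(subject, cfg) {
  f_max <- floor(cfg$primer_error_rate * nchar(cfg$primer_f))
  r_max <- floor(cfg$primer_error_rate * nchar(cfg$primer_r))
  fixed <- c(pattern = FALSE, subject = TRUE)
  fh <- Biostrings::matchPattern(
    Biostrings::DNAString(cfg$primer_f), subject,
    max.mismatch = f_max, with.indels = TRUE, fixed = fixed
  )
  if (length(fh) == 0L) return(NULL)
  rh <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(cfg$primer_r)),
    subject,
    max.mismatch = r_max, with.indels = TRUE, fixed = fixed
  )
  if (length(rh) == 0L) return(NULL)
  f_i <- which.min(IRanges::start(fh))     # forward primer closest to 5'
  r_i <- which.max(IRanges::end(rh))       # reverse primer closest to 3'
  f_end <- IRanges::end(fh)[f_i]
  r_start <- IRanges::start(rh)[r_i]
  if (r_start <= f_end + 1L) return(NULL)  # primers overlap or empty insert
  list(
    insert_start = f_end + 1L, insert_end = r_start - 1L,
    f_start = IRanges::start(fh)[f_i],
    r_end = IRanges::end(rh)[r_i]
  )
}

#' Locate primers, orient a read and trim the primer spans
#'
#' Requires the forward primer at the 5' end and the reverse complement of
#' the reverse primer at the 3' end of the plus orientation, testing both
#' strands. Reads found on the minus strand are reverse-complemented (and
#' their quality string reversed) before trimming, so every returned read
#' is plus-oriented with both primer spans removed. A read lacking either
#' primer at the configured error tolerance is rejected.
#'
#' @param seq DNA string of the read.
#' @param qual integer Phred scores, one per base.
#' @param cfg an [amplicon_config()].
#' @return a list with elements `seq`, `qual`, `flipped` and
#'   `primer_offset` (distance of the outermost primer boundary from the
#'   read end, large values suggesting untrimmed barcodes), or `NULL` when
#'   either primer is absent.
#' @export
match_and_trim_primers <- function(seq, qual, cfg) {
  stopifnot(nchar(seq) > 0L, nchar(seq) == length(qual))
  subj <- Biostrings::DNAString(seq)
  loc <- .locate_primers(subj, cfg)
  flipped <- FALSE
  if (is.null(loc)) {
    subj <- Biostrings::reverseComplement(subj)
    qual <- rev(qual)
    loc <- .locate_primers(subj, cfg)
    flipped <- TRUE
  }
  if (is.null(loc)) return(NULL)
  n <- length(subj)
  list(
    seq = as.character(subj[loc$insert_start:loc$insert_end]),
    qual = qual[loc$insert_start:loc$insert_end],
    flipped = flipped,
    primer_offset = max(loc$f_start - 1L, n - loc$r_end)
  )
}

#' Median read quality with cap-artifact exclusion
#'
#' Median of the per-base Phred scores after excluding positions at or
#' above `q_cap_exclude`, where basecallers pin saturated probabilities
#' (observed as a spike at Q90). If every position is capped, the median of
#' the full vector is returned.
#'
#' @param qual integer Phred scores.
#' @param q_cap_exclude cap threshold (default 90).
#' @return the median quality as a double.
#' @export
#' @examples
#' median_quality(c(10, 20, 30, 90, 90)) # 20
median_quality <- function(qual, q_cap_exclude = 90L) {
  stopifnot(length(qual) >= 1L)
  keep <- qual < q_cap_exclude
  if (!any(keep)) return(median(as.numeric(qual)))
  median(as.numeric(qual[keep]))
}

.attrition_names <- c("no_primer", "bad_quality", "too_short", "too_long", "kept")

.empty_attrition <- function() {
  setNames(integer(length(.attrition_names)), .attrition_names)
}

#' Filter prepared reads on median quality and length
#'
#' Keeps reads whose Q-cap-excluded median quality is at least
#' `cfg$q_min` and whose length lies within the expected amplicon bounds.
#' Each rejected read is counted under its first failing reason
#' (`bad_quality`, then `too_short`, then `too_long`), so the attrition
#' counts always sum to the input count.
#'
#' @param reads a read-set data frame of primer-trimmed reads.
#' @param cfg an [amplicon_config()].
#' @return list with `kept` (read-set data frame) and `log` (named integer
#'   vector of attrition counts).
#' @export
filter_reads <- function(reads, cfg) {
  log <- .empty_attrition()
  if (nrow(reads) == 0L) return(list(kept = reads, log = log))
  medq <- vapply(reads$qual, median_quality,
                 q_cap_exclude = cfg$q_cap_exclude, numeric(1L))
  len <- nchar(reads$seq)
  reason <- rep("kept", nrow(reads))
  reason[len > cfg$max_len] <- "too_long"
  reason[len < cfg$min_len] <- "too_short"
  reason[medq < cfg$q_min] <- "bad_quality"
  tab <- table(factor(reason, levels = .attrition_names))
  log[names(tab)] <- as.integer(tab)
  list(kept = reads[reason == "kept", , drop = FALSE], log = log)
}

#' Prepare one sample's raw reads
#'
#' Full read-preparation stage: primer matching/orientation/trimming,
#' median-quality filtering (Q-cap positions excluded) and expected-length
#' filtering. Emits a warning when trimmed primers sit far (> 30 bp) from
#' the read ends, which usually means barcodes were not removed upstream;
#' barcode trimming is a precondition of this pipeline, not something it
#' attempts itself.
#'
#' @param raw a read-set data frame of raw reads (see [read_fastq()]).
#' @param cfg an [amplicon_config()].
#' @return list with `reads` (prepared read-set data frame) and `log`
#'   (named attrition counts summing to `nrow(raw)`).
#' @export
prepare_sample <- function(raw, cfg) {
  log <- .empty_attrition()
  if (nrow(raw) == 0L) return(list(reads = .empty_read_set(), log = log))
  trimmed <- vector("list", nrow(raw))
  offsets <- integer(0)
  for (i in seq_len(nrow(raw))) {
    m <- match_and_trim_primers(raw$seq[[i]], raw$qual[[i]], cfg)
    if (is.null(m)) next
    trimmed[[i]] <- m
    offsets <- c(offsets, m$primer_offset)
  }
  hit <- !vapply(trimmed, is.null, logical(1L))
  log[["no_primer"]] <- sum(!hit)
  if (length(offsets) > 0L && mean(offsets > 30L) > 0.5) {
    warning(
      "primers found > 30 bp from the read ends in most reads of sample '",
      raw$sample_id[[1L]], "': input may contain untrimmed barcodes/adapters"
    )
  }
  if (!any(hit)) return(list(reads = .empty_read_set(), log = log))
  prep <- .read_set(
    id = raw$id[hit],
    seq = vapply(trimmed[hit], `[[`, character(1L), "seq"),
    qual = lapply(trimmed[hit], `[[`, "qual"),
    sample_id = raw$sample_id[hit],
    flipped = vapply(trimmed[hit], `[[`, logical(1L), "flipped")
  )
  flt <- filter_reads(prep, cfg)
  log[names(flt$log)] <- log[names(flt$log)] + flt$log
  list(reads = flt$kept, log = log)
}
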