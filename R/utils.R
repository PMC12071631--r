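`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement honouring IUPAC ambiguity codes.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp_dna(c("ACGT", "AAWC"))
revcomp_dna <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' GC fraction of DNA strings
#'
#' Fraction of G+C over the full sequence length (ambiguous bases count in
#' the denominator only).
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  ss <- Biostrings::DNAStringSet(x)
  n <- Biostrings::width(ss)
  gc <- Biostrings::letterFrequency(ss, letters = "CG")[, 1L]
  ifelse(n > 0L, gc / n, NA_real_)
}

# Replace IUPAC ambiguity codes by a random concrete base (used by the
# simulator: a sequenced molecule carries concrete bases at degenerate
# primer positions).
.instantiate_iupac <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  amb <- !(chars %in% c("A", "C", "G", "T"))
  if (any(amb)) {
    map <- Biostrings::IUPAC_CODE_MAP
    chars[amb] <- vapply(chars[amb], function(ch) {
      opts <- strsplit(map[[ch]], "", fixed = TRUE)[[1L]]
      opts[sample.int(length(opts), 1L)]
    }, character(1L))
  }
  paste(chars, collapse = "")
}

# Phred integer scores <-> Sanger (+33) ASCII string
.phred_to_string <- function(q) intToUtf8(pmin(q, 93L) + 33L)
.string_to_phred <- function(s) utf8ToInt(s) - 33L

# Container for a set of reads: plain data.frame with a list column of
# integer Phred vectors. Used for both raw and prepared reads.
.read_set <- function(id, seq, qual, sample_id, flipped = NA) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  stopifnot(all(nchar(seq) == lengths(qual)))
  df <- data.frame(
    id = as.character(id),
    seq = as.character(seq),
    sample_id = rep_len(as.character(sample_id), length(id)),
    flipped = rep_len(flipped, length(id)),
    stringsAsFactors = FALSE
  )
  df$qual <- unname(lapply(qual, as.integer))
  df
}

.empty_read_set <- function() {
  df <- data.frame(
    id = character(0), seq = character(0),
    sample_id = character(0), flipped = logical(0),
    stringsAsFactors = FALSE
  )
  df$qual <- list()
  df
}
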