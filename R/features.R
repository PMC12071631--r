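#' Collapse homopolymer runs
#'
#' Replaces every maximal run of a repeated base by a single occurrence
#' (`...XYYYYXXY... -> ...XYX...`). Nanopore reads are least accurate in
#' homopolymer tracts, whose length errors would otherwise split reads of
#' one template across clusters; compression removes run-length information
#' before k-mer counting. Compressed sequences are used only for feature
#' collection, never for consensus building.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector with all runs collapsed.
#' @export
#' @examples
#' compress_homopolymers("GTTTTGGT") # "GTGT"
compress_homopolymers <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) <= 1L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    keep <- c(TRUE, ch[-1L] != ch[-length(ch)])
    paste(ch[keep], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' k-mer signature of a sequence
#'
#' Occurrence counts of all `4^k` DNA words in lexicographic order
#' (A < C < G < T). Windows containing any non-ACGT letter are skipped.
#'
#' @param seq a DNA string (normally homopolymer-compressed).
#' @param k word length (default 6).
#' @return named integer vector of length `4^k`.
#' @export
kmer_signature <- function(seq, k = 6L) {
  if (nchar(seq) < k) {
    stop(structure(
      class = c("too_short_for_k", "error", "condition"),
      list(message = sprintf(
        "sequence of length %d is shorter than k = %d", nchar(seq), k
      ), call = sys.call())
    ))
  }
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
}

# k-mer count matrix over a set of (compressed) sequences; sequences
# shorter than k are dropped with a warning and reported in `dropped`.
.kmer_matrix <- function(seqs, ids, k = 6L) {
  too_short <- nchar(seqs) < k
  if (any(too_short)) {
    warning(sum(too_short), " read(s) shorter than k = ", k,
            " after homopolymer compression; dropped")
  }
  dropped <- ids[too_short]
  seqs <- seqs[!too_short]
  ids <- ids[!too_short]
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k
  )
  rownames(counts) <- ids
  list(counts = counts, read_ids = ids, dropped_ids = dropped)
}

#' Centred log-ratio transform
#'
#' Maps each row `x` of a count matrix to
#' `ln((x_i + pseudocount) / g(x + pseudocount))`, `g` being the geometric
#' mean of the pseudocounted row. k-mer signatures are compositional (their
#' total is tied to read length, not abundance); the CLR removes that
#' constraint so Euclidean geometry downstream is meaningful. Every output
#' row sums to zero.
#'
#' @param counts non-negative numeric matrix.
#' @param pseudocount positive value added to all counts (default 1).
#' @return numeric matrix of the same dimensions.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0, all(counts >= 0))
  lm <- log(counts + pseudocount)
  lm - rowMeans(lm)
}

#' Build the CLR k-mer feature matrix for a read set
#'
#' Homopolymer-compresses each read, counts its `4^k` k-mer signature and
#' applies the centred log-ratio transform. Reads whose compressed sequence
#' is shorter than `k` are dropped with a warning.
#'
#' @param reads a read-set data frame of prepared reads.
#' @param k k-mer length (default 6).
#' @param pseudocount CLR pseudocount (default 1).
#' @return a `feature_matrix` list: `values` (N x 4^k numeric matrix,
#'   rownames = read ids), `read_ids`, `k`.
#' @export
build_features <- function(reads, k = 6L, pseudocount = 1) {
  comp <- compress_homopolymers(reads$seq)
  km <- .kmer_matrix(comp, reads$id, k = k)
  structure(
    list(
      values = clr_transform(km$counts, pseudocount = pseudocount),
      read_ids = km$read_ids,
      k = as.integer(k)
    ),
    class = "feature_matrix"
  )
}
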