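#' Multiply align a cluster's selected reads
#'
#' Aligns the (uncompressed) reads with MAFFT (default parameters) when the
#' binary is on the PATH, otherwise with an internal center-star aligner
#' that satisfies the same contract: equal-length rows whose degapped
#' content reproduces each input read exactly. Per-base Phred qualities are
#' carried through to aligned coordinates (gaps carry no quality).
#'
#' @param seqs character vector of read sequences (>= 2).
#' @param quals list of integer Phred vectors, parallel to `seqs`.
#' @param ids optional read ids (default `r1..rn`).
#' @param method `"auto"` (MAFFT if available), `"mafft"` or
#'   `"centerstar"`.
#' @return a `cluster_msa` list: `aln` (character matrix, reads x columns,
#'   gaps as `"-"`), `qual` (integer matrix, `NA` at gaps), `ids`.
#' @export
align_cluster <- function(seqs, quals, ids = NULL,
                          method = c("auto", "mafft", "centerstar")) {
  method <- match.arg(method)
  stopifnot(length(seqs) >= 2L, length(seqs) == length(quals))
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  if (method == "auto") {
    method <- if (nzchar(Sys.which("mafft"))) "mafft" else "centerstar"
    if (method == "centerstar") {
      warning("MAFFT not found on PATH; using the internal center-star aligner")
    }
  }
  aligned <- switch(method,
    mafft = .mafft_align(seqs),
    centerstar = .center_star_align(seqs)
  )
  .msa_from_gapped(aligned, seqs, quals, ids)
}

.mafft_align <- function(seqs) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  ferr <- tempfile(fileext = ".log")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  writeLines(as.vector(rbind(paste0(">s", seq_along(seqs)), seqs)), fin)
  status <- system2("mafft", c("--quiet", "--thread", "1", fin),
                    stdout = fout, stderr = ferr)
  if (status != 0L) {
    stop("mafft failed (exit ", status, "):\n",
         paste(readLines(ferr, warn = FALSE), collapse = "\n"))
  }
  aln <- Biostrings::readBStringSet(fout)
  aln <- toupper(as.character(aln))
  unname(aln[paste0("s", seq_along(seqs))])
}

# Center-star multiple alignment: global pairwise alignments of every read
# against a center read (the one closest to the median length), merged by
# the "once a gap, always a gap" rule on center coordinates.
.center_star_align <- function(seqs) {
  n <- length(seqs)
  ci <- which.min(abs(nchar(seqs) - median(nchar(seqs))))
  center <- seqs[ci]
  lc <- nchar(center)
  # ins[[i]][j+1]: gap run inserted after center position j (0 = before
  # first) in the pairwise alignment of read i vs the center.
  ins <- vector("list", n)
  gapped_p <- character(n) # pattern (read) rows of the pairwise alignments
  gapped_s <- character(n) # subject (center) rows
  for (i in seq_len(n)) {
    if (i == ci) {
      ins[[i]] <- integer(lc + 1L)
      gapped_p[i] <- center
      gapped_s[i] <- center
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[i], subject = center, type = "global"
    )
    p <- as.character(Biostrings::alignedPattern(pa))
    s <- as.character(Biostrings::alignedSubject(pa))
    gapped_p[i] <- p
    gapped_s[i] <- s
    sch <- strsplit(s, "", fixed = TRUE)[[1L]]
    runs <- integer(lc + 1L)
    pos <- 0L
    for (ch in sch) {
      if (ch == "-") runs[pos + 1L] <- runs[pos + 1L] + 1L else pos <- pos + 1L
    }
    ins[[i]] <- runs
  }
  maxins <- do.call(pmax, ins)
  # re-pad each pairwise pattern row onto the merged coordinate system
  out <- character(n)
  for (i in seq_len(n)) {
    pch <- strsplit(gapped_p[i], "", fixed = TRUE)[[1L]]
    sch <- strsplit(gapped_s[i], "", fixed = TRUE)[[1L]]
    res <- character(0)
    pos <- 0L # center positions consumed
    j <- 1L
    emit_slot <- function(res, slot_len, have) {
      c(res, rep("-", slot_len - have))
    }
    # walk slots: [ins before pos 1] c1 [ins after 1] c2 ... c_lc [ins after lc]
    k <- 1L
    total <- length(pch)
    while (pos <= lc) {
      have <- 0L
      buf <- character(0)
      while (k <= total && sch[k] == "-") {
        buf <- c(buf, pch[k])
        have <- have + 1L
        k <- k + 1L
      }
      res <- c(res, buf, rep("-", maxins[pos + 1L] - have))
      if (pos == lc) break
      res <- c(res, pch[k]) # read char aligned to center position pos+1
      k <- k + 1L
      pos <- pos + 1L
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

.msa_from_gapped <- function(aligned, seqs, quals, ids) {
  widths <- nchar(aligned)
  stopifnot(length(unique(widths)) == 1L)
  n <- length(aligned)
  L <- widths[1L]
  aln <- matrix("-", nrow = n, ncol = L)
  qmat <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    ch <- strsplit(aligned[i], "", fixed = TRUE)[[1L]]
    aln[i, ] <- ch
    idx <- which(ch != "-")
    if (paste(ch[idx], collapse = "") != seqs[i]) {
      stop("internal error: alignment row ", i, " does not reproduce its read")
    }
    qmat[i, idx] <- quals[[i]]
  }
  rownames(aln) <- rownames(qmat) <- ids
  structure(list(aln = aln, qual = qmat, ids = ids), class = "cluster_msa")
}

#' Call the proto-consensus of a cluster alignment
#'
#' Per alignment column, in order:
#' 1. if the gap is strictly the most common symbol, emit `"-"` (a tie
#'    between gap and a letter goes to the letter: deletions are the
#'    dominant nanopore error mode, so gaps must win outright);
#' 2. otherwise, among letters supported by at least `min_support` reads,
#'    the letter with the highest summed Phred quality (quality-weighted
#'    support) is the candidate (ties: higher count, then alphabetic
#'    order);
#' 3. the candidate is emitted only if it is also (tied-)most frequent;
#'    when the most frequent letter carries less quality weight than a
#'    rarer letter, the column is genuinely ambiguous and `"N"` is
#'    emitted;
#' 4. if no letter reaches `min_support`, emit `"N"`.
#'
#' Summed rather than per-base mean quality is used for the comparison in
#' (2)-(3): a mean over a handful of reads is dominated by sampling noise
#' and would flag well-supported columns as ambiguous whenever a few
#' misaligned high-quality bases pile up, whereas the quality-weighted
#' vote only overturns the frequency winner when counts are close and the
#' quality evidence is decisive.
#'
#' `N` symbols in reads carry no vote. Phred values at or above
#' `q_cap_exclude` are basecaller cap artifacts carrying no confidence
#' information (the same reason they are excluded from
#' [median_quality()]): they contribute zero weight to the per-letter
#' quality sum. The result may contain `-` and `N`; see [strip_gaps()]
#' and [trim_polyN()].
#'
#' @param msa a `cluster_msa` from [align_cluster()].
#' @param min_support minimum read support for a called base (default 3).
#' @param q_cap_exclude Phred cap threshold (default 90).
#' @return the proto-consensus string over `{A,C,G,T,N,-}`.
#' @export
call_proto_consensus <- function(msa, min_support = 3L,
                                 q_cap_exclude = 90L) {
  aln <- msa$aln
  qmat <- msa$qual
  if (nrow(aln) < min_support) {
    stop("cluster alignment has fewer rows than min_support = ", min_support)
  }
  bases <- c("A", "C", "G", "T")
  out <- character(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    gap_n <- sum(col == "-")
    counts <- vapply(bases, function(b) sum(col == b), integer(1L))
    maxc <- max(counts)
    if (gap_n > maxc) {
      out[j] <- "-"
      next
    }
    supported <- bases[counts >= min_support]
    if (length(supported) == 0L) {
      out[j] <- "N"
      next
    }
    qweight <- vapply(supported, function(b) {
      q <- qmat[col == b, j]
      sum(q[q < q_cap_exclude])
    }, numeric(1L))
    ord <- order(-qweight, -counts[supported], supported)
    cand <- supported[ord[1L]]
    out[j] <- if (counts[[cand]] == maxc) cand else "N"
  }
  paste(out, collapse = "")
}

#' Remove gaps from a proto-consensus
#'
#' @param proto string over `{A,C,G,T,N,-}`.
#' @return the string with all `-` removed, order preserved.
#' @export
strip_gaps <- function(proto) gsub("-", "", proto, fixed = TRUE)

#' Trim poly-N runs from both ends of a consensus
#'
#' Untrimmed or low-quality read ends accumulate `N` calls at the
#' consensus boundaries; this removes the maximal `N` runs at both ends
#' while keeping interior `N`s.
#'
#' @param seq string over `{A,C,G,T,N}`.
#' @return trimmed string.
#' @export
trim_polyN <- function(seq) gsub("^N+|N+$", "", seq)

#' Assemble the consensus of one cluster
#'
#' Aligns the selected reads, calls the proto-consensus, strips gaps and
#' (optionally) trims terminal poly-N runs.
#'
#' @param seqs,quals,ids the cluster's selected reads (see
#'   [align_cluster()]).
#' @param cluster_label integer or string label recorded in the result.
#' @param min_support minimum read support (default 3); fewer reads than
#'   this is an error (the pipeline skips such clusters beforehand).
#' @param trim trim terminal poly-N (default `TRUE`).
#' @param aligner passed to [align_cluster()] as `method`.
#' @return an `otu_consensus` list: `cluster_label`, `proto`, `final_seq`,
#'   `support` (number of reads aligned), `polished` (`FALSE` until
#'   [polish_consensus()] runs).
#' @export
build_consensus <- function(seqs, quals, ids = NULL, cluster_label = 1L,
                            min_support = 3L, trim = TRUE,
                            aligner = "auto") {
  if (length(seqs) < min_support) {
    stop("cluster has ", length(seqs), " selected reads; min_support = ",
         min_support)
  }
  msa <- align_cluster(seqs, quals, ids, method = aligner)
  proto <- call_proto_consensus(msa, min_support = min_support)
  final <- strip_gaps(proto)
  if (trim) final <- trim_polyN(final)
  structure(
    list(
      cluster_label = cluster_label,
      proto = proto,
      final_seq = final,
      support = length(seqs),
      polished = FALSE
    ),
    class = "otu_consensus"
  )
}

#' Polish a consensus with medaka (optional external tool)
#'
#' Runs `medaka_consensus` with the cluster's reads against the draft
#' consensus when the binary is available. When medaka is absent or exits
#' non-zero the input consensus is returned unchanged with
#' `polished = FALSE` and a warning -- polishing is an optional refinement,
#' never a pipeline requirement.
#'
#' @param consensus an `otu_consensus`.
#' @param seqs,quals,ids the cluster's reads, as for [align_cluster()].
#' @return an `otu_consensus`, possibly with a polished `final_seq`.
#' @export
polish_consensus <- function(consensus, seqs, quals, ids = NULL) {
  medaka <- Sys.which("medaka_consensus")
  if (!nzchar(medaka)) {
    warning("medaka_consensus not found on PATH; consensus left unpolished")
    return(consensus)
  }
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  wd <- tempfile("medaka")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  draft <- file.path(wd, "draft.fasta")
  reads_fq <- file.path(wd, "reads.fastq")
  writeLines(c(">draft", consensus$final_seq), draft)
  write_fastq(.read_set(ids, seqs, quals, "cluster"), reads_fq)
  status <- system2(medaka, c("-i", reads_fq, "-d", draft,
                              "-o", file.path(wd, "out"), "-t", "1"),
                    stdout = FALSE, stderr = FALSE)
  polished_fa <- file.path(wd, "out", "consensus.fasta")
  if (status != 0L || !file.exists(polished_fa)) {
    warning("medaka_consensus failed; consensus left unpolished")
    return(consensus)
  }
  seq <- as.character(Biostrings::readDNAStringSet(polished_fa))[1L]
  consensus$final_seq <- unname(seq)
  consensus$polished <- TRUE
  consensus
}
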