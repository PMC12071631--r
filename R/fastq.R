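#' Read a FASTQ file into a read set
#'
#' Reads Sanger-encoded (Phred+33) FASTQ, plain or gzip-compressed, into the
#' package's read-set data frame (columns `id`, `seq`, `sample_id`,
#' `flipped`, and a list column `qual` of integer Phred scores).
#'
#' @param path path to a `.fastq` or `.fastq.gz` file.
#' @param sample_id sample identifier recorded for every read; defaults to
#'   the file name without extension.
#' @return a read-set data frame.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  qs <- Biostrings::readQualityScaledDNAStringSet(path,
    quality.scoring = "phred"
  )
  if (length(qs) == 0L) return(.empty_read_set())
  ids <- sub("\\s.*$", "", names(qs))
  quals <- as.list(as(Biostrings::quality(qs), "IntegerList"))
  # dropping FASTQ header metadata columns is intended, not a problem
  seqs <- withCallingHandlers(
    as.character(qs),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  .read_set(id = ids, seq = seqs, qual = quals, sample_id = sample_id)
}

#' Write a read set to FASTQ
#'
#' @param reads a read-set data frame.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    qstr <- vapply(reads$qual, .phred_to_string, character(1L))
    lines <- as.vector(rbind(
      paste0("@", reads$id), reads$seq, "+", qstr
    ))
    writeLines(lines, con)
  }
  invisible(path)
}

# Normalise the `samples` argument of run_single()/run_pool(): a named
# character vector of FASTQ paths, a sample-sheet data frame
# (sample_id, path), or a named list of read-set data frames.
.normalise_samples <- function(samples) {
  if (is.data.frame(samples) && all(c("sample_id", "path") %in% names(samples))) {
    samples <- setNames(as.character(samples$path), samples$sample_id)
  }
  if (is.character(samples)) {
    if (is.null(names(samples)) || any(names(samples) == "")) {
      names(samples) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(samples))
    }
    return(lapply(setNames(nm = names(samples)), function(s) {
      read_fastq(samples[[s]], sample_id = s)
    }))
  }
  if (is.list(samples)) {
    stopifnot(!is.null(names(samples)))
    return(lapply(setNames(nm = names(samples)), function(s) {
      df <- samples[[s]]
      df$sample_id <- s
      df
    }))
  }
  stop("`samples` must be named FASTQ paths, a sample sheet, or read sets")
}
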