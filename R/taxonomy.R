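#' Read BLAST+ tabular output
#'
#' Parses `blastn -outfmt "6 qseqid sseqid pident qcovs bitscore evalue
#' stitle"`. Lines with the wrong field count are skipped with a warning.
#'
#' @param path path to the tabular file.
#' @param col_names column names matching the outfmt specification.
#' @return data frame of hits.
#' @export
read_blast_tab <- function(path,
                           col_names = c("qseqid", "sseqid", "pident",
                                         "qcovs", "bitscore", "evalue",
                                         "stitle")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(as.data.frame(setNames(
      rep(list(character(0)), length(col_names)), col_names
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == length(col_names)
  if (any(!ok)) {
    warning(sum(!ok), " malformed BLAST line(s) skipped")
    parts <- parts[ok]
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- col_names
  for (numcol in intersect(c("pident", "qcovs", "bitscore", "evalue"),
                           col_names)) {
    df[[numcol]] <- as.numeric(df[[numcol]])
  }
  df
}

#' Threshold presets for taxonomy assignment
#'
#' `lenient` (coverage >= 60, identity >= 95) suits transparent
#' mock-community profiling where redundancy is acceptable; `strict`
#' (coverage >= 98, identity >= 97) suppresses noise from poorly
#' classified sequences in complex communities.
#'
#' @format named list of `c(min_qcov, min_ident)` pairs.
#' @export
taxonomy_presets <- list(
  lenient = c(min_qcov = 60, min_ident = 95),
  strict = c(min_qcov = 98, min_ident = 97)
)

#' Assign taxonomy to OTUs from BLAST hits
#'
#' For each query, hits meeting BOTH the query-coverage and identity
#' thresholds are considered; the highest-bitscore qualifying hit wins
#' (ties: lowest e-value, then first subject id alphabetically). Queries
#' with no qualifying hit are reported as `"Unclassified"`.
#'
#' @param hits data frame from [read_blast_tab()].
#' @param min_qcov minimum query coverage percentage (default 60).
#' @param min_ident minimum percent identity (default 95).
#' @param preset optional name in [taxonomy_presets]; overrides the two
#'   thresholds.
#' @param query_ids optional vector of all query ids, so queries with no
#'   hits at all still appear (as Unclassified).
#' @return data frame: `otu_id`, `taxonomy`, `identity`, `coverage`,
#'   `bitscore` (NA for unclassified queries).
#' @export
assign_taxonomy <- function(hits, min_qcov = 60, min_ident = 95,
                            preset = NULL, query_ids = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(taxonomy_presets))
    min_qcov <- taxonomy_presets[[preset]][["min_qcov"]]
    min_ident <- taxonomy_presets[[preset]][["min_ident"]]
  }
  queries <- query_ids %||% unique(hits$qseqid)
  rows <- lapply(queries, function(q) {
    h <- hits[hits$qseqid == q &
                hits$qcovs >= min_qcov &
                hits$pident >= min_ident, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(
        otu_id = q, taxonomy = "Unclassified",
        identity = NA_real_, coverage = NA_real_, bitscore = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    best <- h[1L, ]
    tax <- if ("stitle" %in% names(best)) best$stitle else best$sseqid
    data.frame(
      otu_id = q, taxonomy = tax,
      identity = best$pident, coverage = best$qcovs,
      bitscore = best$bitscore, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run blastn and assign taxonomy (external-tool wrapper)
#'
#' Convenience wrapper that shells out to `blastn` against a prepared
#' BLAST database and filters the hits with [assign_taxonomy()]. Requires
#' BLAST+ on the PATH; the tested unit is the parser/filter, not blastn
#' itself.
#'
#' @param otu_fasta path to the OTU FASTA.
#' @param db path to a BLAST nucleotide database.
#' @param ... passed to [assign_taxonomy()].
#' @return see [assign_taxonomy()].
#' @export
blast_and_assign <- function(otu_fasta, db, ...) {
  if (!nzchar(Sys.which("blastn"))) {
    stop("blastn not found on PATH")
  }
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  status <- system2("blastn", c(
    "-query", otu_fasta, "-db", db,
    "-outfmt", shQuote("6 qseqid sseqid pident qcovs bitscore evalue stitle"),
    "-out", out
  ), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn failed (exit ", status, ")")
  ids <- sub("^>(\\S+).*$", "\\1",
             grep("^>", readLines(otu_fasta, warn = FALSE), value = TRUE))
  assign_taxonomy(read_blast_tab(out), query_ids = ids, ...)
}
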