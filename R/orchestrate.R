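#' Pipeline run configuration
#'
#' @param amplicon an [amplicon_config()] (see [amplicon_presets]).
#' @param mode `"single"` (each sample processed independently) or
#'   `"pool"` (joint clustering of all samples with per-sample composition
#'   restored afterwards). Pool mode is recommended for shallow samples or
#'   long amplicons, where per-sample read counts are too small to cluster
#'   reliably.
#' @param k k-mer length for the feature signature (default 6).
#' @param seed seed for the embedding (default 42); the whole pipeline is
#'   deterministic given input + seed.
#' @param min_cluster_size HDBSCAN minimum cluster size; default
#'   `max(5, ceiling(0.001 * N))` at run time.
#' @param min_support minimum reads backing a consensus base (default 3);
#'   clusters whose selected read set is smaller are skipped.
#' @param pseudocount CLR pseudocount (default 1).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15, 0.1).
#' @param trim_polyn trim terminal poly-N from consensus (default `TRUE`).
#' @param polish run medaka polishing when available (default `FALSE`).
#' @param aligner MSA backend passed to [align_cluster()].
#' @return a `run_config` list.
#' @export
run_config <- function(amplicon, mode = c("single", "pool"),
                       k = 6L, seed = 42L,
                       min_cluster_size = NULL, min_support = 3L,
                       pseudocount = 1, n_neighbors = 15L, min_dist = 0.1,
                       trim_polyn = TRUE, polish = FALSE,
                       aligner = "auto") {
  mode <- match.arg(mode)
  stopifnot(inherits(amplicon, "amplicon_config"))
  structure(
    list(
      amplicon = amplicon, mode = mode, k = as.integer(k),
      seed = as.integer(seed), min_cluster_size = min_cluster_size,
      min_support = as.integer(min_support), pseudocount = pseudocount,
      n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
      trim_polyn = trim_polyn, polish = polish, aligner = aligner
    ),
    class = "run_config"
  )
}

.empty_pipeline_result <- function() {
  list(
    otus = list(),
    assignments = data.frame(
      read_id = character(0), sample_id = character(0),
      cluster = integer(0), selected = logical(0),
      x = numeric(0), y = numeric(0), stringsAsFactors = FALSE
    )
  )
}

# Core pipeline over one set of prepared reads:
# features -> PCA -> UMAP -> HDBSCAN -> selection -> consensus per cluster.
.run_pipeline <- function(reads, cfg) {
  if (nrow(reads) < 2L) {
    warning("fewer than 2 prepared reads survive filtering: no clustering")
    return(.empty_pipeline_result())
  }
  fm <- build_features(reads, k = cfg$k, pseudocount = cfg$pseudocount)
  reads <- reads[match(fm$read_ids, reads$id), , drop = FALSE]
  n <- nrow(reads)
  if (n < 2L) return(.empty_pipeline_result())
  mcs <- cfg$min_cluster_size %||% max(5L, ceiling(0.001 * n))
  pcs <- reduce_pca(fm)
  ec <- .embed_and_cluster(pcs, seed = cfg$seed,
                           n_neighbors = cfg$n_neighbors,
                           min_dist = cfg$min_dist,
                           min_cluster_size = mcs)
  cs <- .apply_selection(ec$cluster_set, reads)
  sel_ids <- unlist(cs$selected, use.names = FALSE)
  otus <- list()
  for (nm in names(cs$clusters)) {
    ids <- cs$selected[[nm]]
    if (length(ids) < cfg$min_support) {
      warning("cluster ", nm, ": only ", length(ids),
              " reads after selection (< min_support); consensus skipped")
      next
    }
    idx <- match(ids, reads$id)
    cons <- build_consensus(
      reads$seq[idx], reads$qual[idx], ids = ids,
      cluster_label = as.integer(sub("otu_", "", nm)),
      min_support = cfg$min_support, trim = cfg$trim_polyn,
      aligner = cfg$aligner
    )
    if (cfg$polish) {
      cons <- polish_consensus(cons, reads$seq[idx], reads$qual[idx], ids)
    }
    otus[[nm]] <- cons
  }
  coords <- ec$embedding$coords
  list(
    otus = otus,
    assignments = data.frame(
      read_id = reads$id,
      sample_id = reads$sample_id,
      cluster = unname(cs$labels[reads$id]),
      selected = reads$id %in% sel_ids,
      x = coords[, 1L], y = coords[, 2L],
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  )
}

# Counts and relative abundances from an assignment table. Noise reads
# (cluster -1) and clusters without a consensus are excluded; the relative
# denominator is the sample's clustered (non-noise) read count.
.abundance_from_assignments <- function(assignments, otu_ids, sample_ids) {
  counts <- matrix(0L, nrow = length(otu_ids), ncol = length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  if (nrow(assignments) > 0L && length(otu_ids) > 0L) {
    a <- assignments[assignments$otu_id %in% otu_ids, , drop = FALSE]
    if (nrow(a) > 0L) {
      tab <- table(factor(a$otu_id, levels = otu_ids),
                   factor(a$sample_id, levels = sample_ids))
      counts[] <- as.integer(tab)
    }
  }
  totals <- colSums(counts)
  rel <- sweep(counts, 2L, ifelse(totals > 0, totals, 1), "/")
  rel[, totals == 0] <- NA_real_
  list(counts = counts, rel = rel)
}

.finalise_result <- function(mode, otus, assignments, attrition, cfg,
                             sample_ids) {
  assignments$otu_id <- ifelse(
    assignments$cluster == -1L, NA_character_,
    paste0(assignments$otu_prefix, "otu_", assignments$cluster)
  )
  ab <- .abundance_from_assignments(assignments, names(otus), sample_ids)
  assignments$otu_prefix <- NULL
  structure(
    list(
      mode = mode, otus = otus,
      counts = ab$counts, rel_abundance = ab$rel,
      assignments = assignments, attrition = attrition, config = cfg
    ),
    class = "nanotu_result"
  )
}

#' Run the pipeline on each sample independently (single mode)
#'
#' @param samples named character vector of FASTQ paths, a sample sheet
#'   data frame (`sample_id`, `path`), or a named list of read-set data
#'   frames.
#' @param cfg a [run_config()].
#' @return a `nanotu_result`: `otus` (named list of `otu_consensus`,
#'   keyed `<sample>.otu_<k>`), `counts` and `rel_abundance` (OTU x sample
#'   matrices; relative abundances are over each sample's clustered,
#'   non-noise reads), `assignments` (per-read table with cluster label,
#'   selection flag and embedding coordinates), `attrition` (per-sample
#'   read-loss counts), `config`.
#' @export
run_single <- function(samples, cfg) {
  sets <- .normalise_samples(samples)
  sample_ids <- names(sets)
  otus <- list()
  assignments <- list()
  attrition <- list()
  for (s in sample_ids) {
    prep <- prepare_sample(sets[[s]], cfg$amplicon)
    attrition[[s]] <- prep$log
    res <- .run_pipeline(prep$reads, cfg)
    if (length(res$otus) > 0L) {
      names(res$otus) <- paste0(s, ".", names(res$otus))
      otus <- c(otus, res$otus)
    }
    if (nrow(res$assignments) > 0L) {
      res$assignments$otu_prefix <- paste0(s, ".")
      assignments[[s]] <- res$assignments
    }
  }
  assignments <- if (length(assignments) > 0L) {
    do.call(rbind, c(assignments, make.row.names = FALSE))
  } else {
    cbind(.empty_pipeline_result()$assignments,
          otu_prefix = character(0))
  }
  attr_df <- as.data.frame(do.call(rbind, attrition))
  attr_df <- cbind(sample_id = sample_ids, attr_df)
  rownames(attr_df) <- NULL
  .finalise_result("single", otus, assignments, attr_df, cfg, sample_ids)
}

#' Run the pipeline jointly over all samples (pool mode)
#'
#' All samples' prepared reads are embedded and clustered together (one
#' feature matrix, sample provenance kept per read), one consensus is
#' built per pooled cluster, and each sample's composition is restored by
#' counting its reads in every cluster. This detects minor community
#' members whose per-sample read counts are too small to form a cluster
#' alone.
#'
#' @inheritParams run_single
#' @return a `nanotu_result` (see [run_single()]); OTU ids are unprefixed
#'   (`otu_1`, ...) as clusters span samples.
#' @export
run_pool <- function(samples, cfg) {
  sets <- .normalise_samples(samples)
  sample_ids <- names(sets)
  attrition <- list()
  prepped <- list()
  for (s in sample_ids) {
    prep <- prepare_sample(sets[[s]], cfg$amplicon)
    attrition[[s]] <- prep$log
    prepped[[s]] <- prep$reads
  }
  pooled <- do.call(rbind, c(prepped, make.row.names = FALSE))
  res <- .run_pipeline(pooled, cfg)
  if (nrow(res$assignments) > 0L) res$assignments$otu_prefix <- ""
  attr_df <- as.data.frame(do.call(rbind, attrition))
  attr_df <- cbind(sample_id = sample_ids, attr_df)
  rownames(attr_df) <- NULL
  .finalise_result("pool", res$otus, res$assignments, attr_df, cfg,
                   sample_ids)
}

#' @export
print.nanotu_result <- function(x, ...) {
  cat("nanotu result (", x$mode, " mode)\n", sep = "")
  cat("  samples: ", paste(colnames(x$counts), collapse = ", "), "\n",
      sep = "")
  cat("  OTUs:    ", length(x$otus), "\n", sep = "")
  for (nm in names(x$otus)) {
    o <- x$otus[[nm]]
    cat(sprintf("    %-16s length %5d  support %4d%s\n", nm,
                nchar(o$final_seq), o$support,
                if (o$polished) "  polished" else ""))
  }
  invisible(x)
}

#' Write pipeline results to an output directory
#'
#' Emits `otus.fasta` (pool mode) or `otus_<sample>.fasta` (single mode)
#' with headers `>otu_<label> support=<n> sample=<id|pooled>`, the OTU
#' count and relative-abundance tables, the per-read cluster table, the
#' attrition log and the run configuration.
#'
#' @param result a `nanotu_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_line <- function(nm) {
    o <- result$otus[[nm]]
    smp <- if (result$mode == "pool") "pooled" else sub("\\.otu_.*$", "", nm)
    c(sprintf(">otu_%s support=%d sample=%s", o$cluster_label, o$support,
              smp),
      o$final_seq)
  }
  if (result$mode == "pool") {
    writeLines(unlist(lapply(names(result$otus), fasta_line)),
               file.path(dir, "otus.fasta"))
  } else {
    for (s in colnames(result$counts)) {
      nms <- grep(paste0("^", s, "\\.otu_"), names(result$otus),
                  value = TRUE)
      writeLines(unlist(lapply(nms, fasta_line)),
                 file.path(dir, paste0("otus_", s, ".fasta")))
    }
  }
  wt <- function(m, f) {
    df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  wt(result$counts, "otu_table.tsv")
  wt(result$rel_abundance, "otu_table_rel.tsv")
  write.table(result$assignments, file.path(dir, "clusters.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(result$attrition, file.path(dir, "attrition.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  cfg$amplicon <- unclass(cfg$amplicon)
  jsonlite::write_json(unclass(cfg), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
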