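#' Reduce a feature matrix by PCA
#'
#' Projects the CLR k-mer matrix onto its leading principal components
#' (default 30), which suppresses noise in the 4096-dimensional signature
#' space and speeds up the nonlinear embedding that follows. The effective
#' number of components is capped by the matrix rank bound
#' `min(n_components, N, 4^k)`.
#'
#' @param fm a `feature_matrix` from [build_features()], or a plain numeric
#'   matrix.
#' @param n_components requested number of components (default 30).
#' @return numeric matrix N x n_eff with rownames carrying read ids;
#'   columns ordered by decreasing explained variance.
#' @export
reduce_pca <- function(fm, n_components = 30L) {
  x <- if (is.matrix(fm)) fm else fm$values
  if (nrow(x) < 2L) {
    stop(structure(
      class = c("insufficient_reads", "error", "condition"),
      list(message = "PCA requires at least 2 reads", call = sys.call())
    ))
  }
  n_eff <- min(n_components, nrow(x), ncol(x))
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_eff)
  p$x[, seq_len(min(n_eff, ncol(p$x))), drop = FALSE]
}

.python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (needed for UMAP/HDBSCAN)")
}

# Run the bundled python worker on a numeric matrix; returns the parsed
# output matrix. mode: "umap", "hdbscan" or "both".
.run_reduce_cluster <- function(x, mode, seed = 42L, n_neighbors = 15L,
                                min_dist = 0.1, min_cluster_size = 5L,
                                min_samples = 5L,
                                cluster_selection_epsilon = 0.5,
                                allow_single_cluster = TRUE) {
  script <- system.file("python", "reduce_cluster.py", package = "nanotu")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".tsv")
  fout <- tempfile(fileext = ".tsv")
  ferr <- tempfile(fileext = ".log")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
              fin, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  status <- system2(.python_bin(), c(
    script, mode,
    "--infile", fin, "--outfile", fout,
    "--seed", as.integer(seed),
    "--n-neighbors", as.integer(n_neighbors),
    "--min-dist", format(min_dist),
    "--min-cluster-size", as.integer(min_cluster_size),
    "--min-samples", as.integer(min_samples),
    "--cluster-selection-epsilon", format(cluster_selection_epsilon),
    if (!allow_single_cluster) "--no-single-cluster"
  ), stdout = ferr, stderr = ferr)
  if (status != 0L) {
    stop("embedding/clustering worker failed (exit ", status, "):\n",
         paste(readLines(ferr, warn = FALSE), collapse = "\n"))
  }
  as.matrix(read.delim(fout, header = FALSE))
}

#' Embed principal components to 2-D with UMAP
#'
#' Nonlinear reduction of the PCA scores to a 2-D map in which reads from
#' one template form a dense blob. Runs seeded and single-threaded, so the
#' same input and seed always give identical coordinates. `n_neighbors` is
#' clamped to N-1 (with a warning) for very small inputs; inputs of fewer
#' than 4 rows skip UMAP and return the first two (zero-padded) input
#' columns, since a neighbourhood graph is meaningless there.
#'
#' @param pcs numeric matrix of PCA scores (rows = reads).
#' @param seed integer random seed.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @return a `nanotu_embedding` list: `coords` (N x 2 matrix, rownames =
#'   read ids), `seed`.
#' @export
embed_umap <- function(pcs, seed = 42L, n_neighbors = 15L, min_dist = 0.1) {
  stopifnot(is.matrix(pcs), all(is.finite(pcs)))
  n <- nrow(pcs)
  if (n < 4L) {
    warning("fewer than 4 reads: returning leading input columns as the embedding")
    coords <- cbind(
      pcs[, 1L],
      if (ncol(pcs) >= 2L) pcs[, 2L] else rep(0, n)
    )
  } else {
    if (n_neighbors >= n) {
      warning("n_neighbors clamped to N - 1 = ", n - 1L)
      n_neighbors <- n - 1L
    }
    coords <- .run_reduce_cluster(pcs, "umap", seed = seed,
                                  n_neighbors = n_neighbors,
                                  min_dist = min_dist)
  }
  dimnames(coords) <- list(rownames(pcs), c("x", "y"))
  structure(list(coords = coords, seed = as.integer(seed)),
            class = "nanotu_embedding")
}

# Renumber raw HDBSCAN labels: -1 stays noise; clusters become 1..K in
# decreasing size order (ties broken by original label) so output ordering
# is stable.
.relabel_by_size <- function(labels) {
  lab <- labels
  cl <- sort(unique(lab[lab != -1L]))
  if (length(cl) == 0L) return(lab)
  sizes <- vapply(cl, function(l) sum(lab == l), integer(1L))
  ord <- cl[order(-sizes, cl)]
  out <- lab
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

#' Cluster a 2-D embedding with HDBSCAN
#'
#' Density-based clustering (Euclidean metric) of the UMAP coordinates;
#' points in low-density regions get the noise label -1. Clusters are
#' renumbered 1..K by decreasing size. If fewer points than
#' `min_cluster_size` are supplied, everything is noise by definition and
#' the worker is not invoked.
#'
#' The defaults decouple `min_samples` from `min_cluster_size`, allow a
#' single-cluster solution and merge sub-clusters within a small embedding
#' distance. A sample containing one amplicon variant embeds as a diffuse
#' cloud with no density contrast; under HDBSCAN's conservative defaults
#' such samples come back all-noise, while these settings recover the
#' single cluster and leave well-separated multi-variant embeddings
#' unchanged.
#'
#' @param emb a `nanotu_embedding` from [embed_umap()], or an N x 2 matrix.
#' @param min_cluster_size smallest group HDBSCAN may call a cluster.
#' @param min_samples density-estimation neighbourhood size (default 5).
#' @param cluster_selection_epsilon merge radius in embedding units
#'   (default 0.5).
#' @param allow_single_cluster permit a lone root cluster (default
#'   `TRUE`).
#' @return a `cluster_set` list: `labels` (integer vector, -1 = noise,
#'   names = read ids), `clusters` (named list label -> member read ids),
#'   `selected` (filled by [select_cluster_reads()] via the pipeline;
#'   initialised to the full membership).
#' @export
cluster_hdbscan <- function(emb, min_cluster_size = 5L, min_samples = 5L,
                            cluster_selection_epsilon = 0.5,
                            allow_single_cluster = TRUE) {
  coords <- if (is.matrix(emb)) emb else emb$coords
  stopifnot(ncol(coords) == 2L)
  n <- nrow(coords)
  if (n < min_cluster_size || n < 2L) {
    warning("fewer points than min_cluster_size: all reads labelled noise")
    labels <- rep(-1L, n)
  } else {
    out <- .run_reduce_cluster(
      coords, "hdbscan", min_cluster_size = min_cluster_size,
      min_samples = min_samples,
      cluster_selection_epsilon = cluster_selection_epsilon,
      allow_single_cluster = allow_single_cluster
    )
    labels <- as.integer(out[, 1L])
  }
  labels <- .relabel_by_size(labels)
  names(labels) <- rownames(coords)
  .new_cluster_set(labels)
}

.new_cluster_set <- function(labels) {
  cl <- sort(unique(labels[labels != -1L]))
  if (length(cl) == 0L) {
    warning("no clusters found: all reads are noise")
    clusters <- setNames(list(), character(0))
  } else {
    clusters <- lapply(setNames(cl, paste0("otu_", cl)), function(l) {
      names(labels)[labels == l]
    })
  }
  structure(
    list(labels = labels, clusters = clusters, selected = clusters),
    class = "cluster_set"
  )
}

# One python invocation doing UMAP then HDBSCAN; numerically identical to
# embed_umap() followed by cluster_hdbscan() but avoids a second
# interpreter start-up. Used by the pipeline.
.embed_and_cluster <- function(pcs, seed, n_neighbors, min_dist,
                               min_cluster_size) {
  n <- nrow(pcs)
  # degenerate input: all reads identical in feature space (e.g. error-free
  # duplicates). A neighbourhood embedding is meaningless; the set is one
  # cluster by definition (or noise, if below min_cluster_size).
  if (n >= 2L && max(abs(sweep(pcs, 2L, pcs[1L, ]))) < 1e-9) {
    coords <- matrix(0, nrow = n, ncol = 2L,
                     dimnames = list(rownames(pcs), c("x", "y")))
    labels <- rep(if (n >= min_cluster_size) 1L else -1L, n)
    names(labels) <- rownames(pcs)
    return(list(
      embedding = structure(list(coords = coords, seed = as.integer(seed)),
                            class = "nanotu_embedding"),
      cluster_set = suppressWarnings(.new_cluster_set(labels))
    ))
  }
  if (n < 4L) {
    emb <- embed_umap(pcs, seed = seed, n_neighbors = n_neighbors,
                      min_dist = min_dist)
    cs <- suppressWarnings(cluster_hdbscan(emb, min_cluster_size))
    return(list(embedding = emb, cluster_set = cs))
  }
  nn <- min(n_neighbors, n - 1L)
  out <- .run_reduce_cluster(pcs, "both", seed = seed, n_neighbors = nn,
                             min_dist = min_dist,
                             min_cluster_size = min_cluster_size)
  coords <- out[, 1:2, drop = FALSE]
  dimnames(coords) <- list(rownames(pcs), c("x", "y"))
  labels <- .relabel_by_size(as.integer(out[, 3L]))
  names(labels) <- rownames(pcs)
  list(
    embedding = structure(list(coords = coords, seed = as.integer(seed)),
                          class = "nanotu_embedding"),
    cluster_set = suppressWarnings(.new_cluster_set(labels))
  )
}

#' Select a cluster's reads for consensus building
#'
#' Not every member of a cluster should enter the multiple alignment:
#' length outliers (|len - mean| > 10 bp) and GC-composition outliers
#' (|GC - mean| > 2 population SD) are excluded, computed over the
#' cluster's members on the uncompressed reads.
#'
#' @param lengths integer read lengths of the cluster members.
#' @param gc numeric GC fractions of the cluster members.
#' @param len_window half-width of the length window in bp (default 10).
#' @param gc_sd number of GC standard deviations kept (default 2).
#' @return logical vector: `TRUE` for reads to keep.
#' @export
select_cluster_reads <- function(lengths, gc, len_window = 10, gc_sd = 2) {
  stopifnot(length(lengths) == length(gc), length(lengths) >= 1L)
  mu_len <- mean(lengths)
  mu_gc <- mean(gc)
  sigma_gc <- sqrt(mean((gc - mu_gc)^2)) # population SD
  abs(lengths - mu_len) <= len_window & abs(gc - mu_gc) <= gc_sd * sigma_gc
}

# Apply per-cluster read selection to a cluster_set given the reads.
.apply_selection <- function(cs, reads) {
  len <- setNames(nchar(reads$seq), reads$id)
  gc <- setNames(gc_fraction(reads$seq), reads$id)
  cs$selected <- lapply(cs$clusters, function(ids) {
    keep <- select_cluster_reads(len[ids], gc[ids])
    ids[keep]
  })
  cs
}
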