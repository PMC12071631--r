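# Two well-separated blobs in feature space, used by several blocks below.
.make_blobs <- function(n_per = 60, dim = 10, sep = 12, seed = 17) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * dim, 0, 1), ncol = dim),
    matrix(rnorm(n_per * dim, sep, 1), ncol = dim)
  )
  rownames(x) <- paste0("r", seq_len(2 * n_per))
  x
}

test_that("PCA reduction caps components by rank and orders by variance", {
  set.seed(8)
  m <- matrix(rnorm(1000 * 50), nrow = 1000)
  pcs <- reduce_pca(m, n_components = 30)
  expect_equal(dim(pcs), c(1000, 30))
  v <- apply(pcs, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  expect_true(all(abs(colMeans(pcs)) < 1e-8)) # centred

  small <- matrix(rnorm(10 * 4096), nrow = 10)
  expect_equal(dim(reduce_pca(small)), c(10, 10))

  expect_error(reduce_pca(matrix(1, 1, 5)), class = "insufficient_reads")
})

test_that("UMAP embedding is 2-D, deterministic under a fixed seed, and separates blobs", {
  x <- .make_blobs()
  e1 <- embed_umap(x, seed = 7)
  expect_s3_class(e1, "nanotu_embedding")
  expect_equal(dim(e1$coords), c(120, 2))
  expect_true(all(is.finite(e1$coords)))

  e2 <- embed_umap(x, seed = 7)
  expect_identical(e1$coords, e2$coords)

  # blob separation: centroid distance exceeds within-blob spread
  c1 <- colMeans(e1$coords[1:60, ])
  c2 <- colMeans(e1$coords[61:120, ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- max(
    sqrt(rowSums(sweep(e1$coords[1:60, ], 2, c1)^2)),
    sqrt(rowSums(sweep(e1$coords[61:120, ], 2, c2)^2))
  )
  expect_gt(between, within)
})

test_that("n_neighbors is clamped for tiny inputs", {
  x <- .make_blobs(n_per = 5, seed = 4)
  expect_warning(e <- embed_umap(x, seed = 1, n_neighbors = 50),
                 "clamped")
  expect_equal(dim(e$coords), c(10, 2))
})

test_that("HDBSCAN recovers blob structure and labels sparse data noise", {
  x <- .make_blobs()
  emb <- embed_umap(x, seed = 7)
  cs <- cluster_hdbscan(emb, min_cluster_size = 10)
  expect_s3_class(cs, "cluster_set")
  expect_equal(length(cs$clusters), 2L)
  expect_setequal(unique(cs$labels), c(1L, 2L))
  # each blob lands in exactly one cluster
  expect_equal(length(unique(cs$labels[1:60])), 1L)
  expect_equal(length(unique(cs$labels[61:120])), 1L)
  expect_true(all(cs$labels[1:60] != cs$labels[61:120]))
  # clusters renumbered by decreasing size: sizes non-increasing
  sizes <- lengths(cs$clusters)
  expect_true(all(diff(sizes) <= 0))

  # partition property: every read is noise or in exactly one cluster
  member_of <- table(unlist(cs$clusters))
  expect_true(all(member_of == 1))
  expect_setequal(names(cs$labels)[cs$labels != -1], names(member_of))

  # fewer points than min_cluster_size: everything is noise, no worker call
  tiny <- matrix(rnorm(40), ncol = 2,
                 dimnames = list(paste0("r", 1:20), NULL))
  expect_warning(cs2 <- cluster_hdbscan(tiny, min_cluster_size = 25),
                 "noise")
  expect_true(all(cs2$labels == -1L))
  expect_equal(length(cs2$clusters), 0L)
})

test_that("cluster read selection applies the length and GC windows", {
  # all members identical: sigma = 0, everything selected
  expect_true(all(select_cluster_reads(rep(100, 5), rep(0.5, 5))))

  # length outlier at mu +/- > 10 bp excluded
  len <- c(rep(100, 9), 115)
  keep <- select_cluster_reads(len, rep(0.5, 10))
  expect_false(keep[10])
  expect_true(all(keep[1:9]))

  # GC outlier beyond 2 population SD excluded
  set.seed(6)
  gc <- c(rnorm(30, 0.50, 0.01))
  gc[31] <- mean(gc[1:30]) + 2.5 * sqrt(mean((gc - mean(gc))^2))
  gc[31] <- 0.65 # far beyond 2 sigma of the tight core
  keep <- select_cluster_reads(rep(100, 31), gc)
  expect_false(keep[31])
})
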