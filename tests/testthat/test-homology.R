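# Hit filtering, similarity graph construction, Markov clustering and
# silhouette-based inflation selection.

make_hits <- function(n, seed) {
  set.seed(seed)
  data.frame(query = paste0("q", sample(50, n, TRUE)),
             subject = paste0("s", sample(50, n, TRUE)),
             evalue = 10^runif(n, -60, 0),
             coverage = runif(n),
             bitscore = runif(n, 50, 500))
}

test_that("hit filtering applies both thresholds and is idempotent", {
  hits <- data.frame(query = c("a", "b"), subject = c("x", "y"),
                     evalue = c(1e-25, 1e-25), coverage = c(0.5, 0.39))
  kept <- filter_hits(hits)
  expect_equal(kept$query, "a")       # 0.39 fails the 40% coverage rule

  big <- make_hits(1000, seed = 42)
  kept <- filter_hits(big, max_e = 1e-10, min_cov = 0.3)
  brute <- big[big$evalue <= 1e-10 & big$coverage >= 0.3, ]
  expect_identical(kept, brute)
  expect_identical(filter_hits(kept, max_e = 1e-10, min_cov = 0.3), kept)
})

test_that("tabular hit parsing computes reference coverage and flags bad rows", {
  tmp <- tempfile()
  rows <- c(paste(c("g1", "ref1", 98, 80, 1, 0, 1, 80, 1, 80, "1e-30", 200),
                  collapse = "\t"),
            paste(c("g2", "g3", 95, 50, 2, 0, 1, 50, 1, 50, "1e-10", 100),
                  collapse = "\t"))
  writeLines(rows, tmp)
  hits <- read_blast_hits(tmp, ref_lengths = c(ref1 = 100))
  expect_equal(hits$coverage, c(0.8, NA))
  expect_equal(nrow(filter_hits(hits, max_e = 1e-5, min_cov = 0.4)), 1L)

  writeLines(c(rows, "bad\trow"), tmp)
  expect_error(read_blast_hits(tmp, c(ref1 = 100)), "line 3")
})

test_that("similarity graph weights are capped, merged and symmetric", {
  hits <- data.frame(query = c("a", "b", "a", "c", "c"),
                     subject = c("b", "a", "a", "d", "d"),
                     evalue = c(1e-30, 1e-40, 1e-99, 0, 1e-50))
  g <- build_similarity_graph(hits, cap = 200)
  expect_equal(g$adj["a", "b"], 40)     # max of the reciprocal pair
  expect_equal(g$adj["b", "a"], 40)
  expect_equal(g$adj["a", "a"], 0)      # self-hit dropped
  expect_equal(g$adj["c", "d"], 200)    # E = 0 capped
  hits2 <- data.frame(query = "x", subject = "y", evalue = 1e-50)
  expect_equal(build_similarity_graph(hits2)$adj["x", "y"], 50)
})

test_that("MCL separates components and respects graph structure", {
  ids <- paste0("s", 1:9)
  adj <- matrix(0, 9, 9, dimnames = list(ids, ids))
  adj[1:4, 1:4] <- 50; adj[5:8, 5:8] <- 50
  diag(adj) <- 0
  g <- similarity_graph(adj)
  cl <- mcl_cluster(g, 2)
  expect_equal(cl$n_clusters, 3L)       # two cliques + singleton s9
  expect_equal(length(unique(cl$labels[1:4])), 1L)
  expect_equal(length(unique(cl$labels[5:8])), 1L)
  expect_false(cl$labels[1] == cl$labels[5])
  expect_setequal(names(cl$labels), ids)  # partition covers every node

  # weakly joined cliques split at moderate inflation
  adj[4, 5] <- adj[5, 4] <- 1
  cl2 <- mcl_cluster(similarity_graph(adj), 2)
  expect_equal(unname(cl2$labels[1:4]), rep(cl2$labels[[1]], 4))
  expect_equal(unname(cl2$labels[5:8]), rep(cl2$labels[[5]], 4))
  expect_false(cl2$labels[1] == cl2$labels[5])

  expect_error(mcl_cluster(g, 1), "inflation")
})

test_that("raising inflation never merges disconnected components", {
  pg <- planted_block_graph(2, 4, intra_w = 50, inter_w = 0, seed = 3)
  for (I in c(1.4, 2, 4, 6)) {
    cl <- mcl_cluster(pg$graph, I)
    expect_gte(cl$n_clusters, 2L)
    agree <- table(cl$labels, pg$truth[names(cl$labels)])
    expect_true(all(rowSums(agree > 0) == 1))  # no cluster spans blocks
  }
})

test_that("silhouette selection recovers planted blocks and breaks ties low", {
  pg <- planted_block_graph(3, 5, seed = 11)
  sel <- select_inflation(pg$graph)
  expect_true(same_partition(sel$best$labels, pg$truth))
  expect_equal(nrow(sel$table), 5L)
  # candidates 1.4..6 all give the identical 3-block partition: tie goes
  # to the smallest informative inflation
  defined <- sel$table[!is.na(sel$table$avg_silhouette), ]
  expect_equal(sel$best$inflation, min(defined$inflation))

  # permutation invariance of the selected partition
  perm <- sample(rownames(pg$graph$adj))
  g2 <- similarity_graph(pg$graph$adj[perm, perm], cap = pg$graph$cap)
  sel2 <- select_inflation(g2)
  expect_true(same_partition(sel2$best$labels, sel$best$labels))
})

test_that("silhouette is undefined when everything clusters together", {
  ids <- c("a", "b", "c")
  adj <- matrix(50, 3, 3, dimnames = list(ids, ids)); diag(adj) <- 0
  expect_error(select_inflation(similarity_graph(adj), c(1.2, 2)),
               "silhouette undefined")
})

test_that("single-copy locus selection applies the strict 95% rule", {
  tab <- rbind(mostly_single = c(rep(1, 45), 2),     # 45/46 = 0.978
               borderline = c(rep(1, 43), 2, 2, 0),  # 43/46 = 0.935
               all_single = rep(1, 46))
  expect_setequal(select_single_copy_loci(tab),
                  c("mostly_single", "all_single"))

  set.seed(9)
  rt <- matrix(rpois(200 * 12, 1), 200, 12,
               dimnames = list(paste0("L", 1:200), NULL))
  got <- select_single_copy_loci(rt, min_fraction = 0.6)
  brute <- rownames(rt)[apply(rt, 1, function(r) mean(r == 1) > 0.6)]
  expect_setequal(got, brute)

  expect_warning(out <- select_single_copy_loci(matrix(nrow = 0, ncol = 0)),
                 "empty")
  expect_length(out, 0L)
})
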