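# Gene-family construction from all-vs-all homology hits: e-value/coverage
# filtering, log-e-value similarity graph, Markov clustering (implemented
# here), silhouette-based inflation selection, and single-copy locus
# selection for species-tree work. Sequence search itself is a commodity
# step and is consumed as a tabular hit file.

#' Read BLAST-style tabular hits
#'
#' Reads a 12-column tabular hit file (outfmt-6 dialect: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore). Coverage is computed against a designated reference set
#' (the experimentally sequenced family homologs): alignment length
#' divided by the reference sequence length, taking the better value when
#' both query and subject are references; hits touching no reference get
#' `NA` coverage and fall at the filtering step.
#'
#' @param path path to the tab-separated hit file.
#' @param ref_lengths named numeric vector: reference id -> sequence length.
#' @return data.frame with columns query, subject, evalue, coverage,
#'   bitscore.
#' @export
read_blast_hits <- function(path, ref_lengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0)
    stop("malformed hit row at line ", bad[1], ": expected 12 columns, got ",
         length(parts[[bad[1]]]))
  m <- do.call(rbind, parts)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  len <- suppressWarnings(as.numeric(m[, 4]))
  bs <- suppressWarnings(as.numeric(m[, 12]))
  bad <- which(is.na(ev) | is.na(len) | ev < 0)
  if (length(bad) > 0) stop("malformed hit row at line ", bad[1],
                            ": bad e-value or alignment length")
  cov_q <- len / ref_lengths[m[, 1]]
  cov_s <- len / ref_lengths[m[, 2]]
  coverage <- pmin(pmax(cov_q, cov_s, na.rm = TRUE), 1)
  coverage[is.na(cov_q) & is.na(cov_s)] <- NA_real_
  data.frame(query = m[, 1], subject = m[, 2], evalue = ev,
             coverage = coverage, bitscore = bs)
}

#' Filter homology hits on e-value and reference coverage
#'
#' Retains hits with `evalue <= max_e` and `coverage >= min_cov`
#' (missing coverage fails the rule). Row order is preserved.
#'
#' @param hits data.frame with columns evalue and coverage
#'   (see [read_blast_hits()]).
#' @param max_e maximum e-value (default 1e-20).
#' @param min_cov minimum reference coverage (default 0.40).
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, max_e = 1e-20, min_cov = 0.40) {
  stopifnot(is.data.frame(hits), all(c("evalue", "coverage") %in% names(hits)))
  if (max_e < 0 || min_cov < 0 || min_cov > 1)
    stop("thresholds out of range")
  keep <- !is.na(hits$evalue) & hits$evalue <= max_e &
    !is.na(hits$coverage) & hits$coverage >= min_cov
  hits[keep, , drop = FALSE]
}

#' Build a log-e-value similarity graph from filtered hits
#'
#' Edge weight `w(i, j) = min(-log10(E), cap)`; an e-value reported as 0
#' maps to the cap. Reciprocal hits are merged by taking the maximum
#' weight, and self-hits are dropped.
#'
#' @param hits data.frame with columns query, subject, evalue.
#' @param cap maximum weight (default 200).
#' @return object of class `similarity_graph`: list with `adj` (symmetric
#'   weighted adjacency matrix, zero diagonal) and `cap`.
#' @export
build_similarity_graph <- function(hits, cap = 200) {
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "evalue") %in% names(hits)))
  w <- -log10(hits$evalue)
  w[!is.finite(w) | w > cap] <- cap
  w[w < 0] <- 0
  keep <- hits$query != hits$subject
  q <- hits$query[keep]; s <- hits$subject[keep]; w <- w[keep]
  nodes <- sort(unique(c(hits$query, hits$subject)))
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (k in seq_along(w)) {
    i <- q[k]; j <- s[k]
    if (w[k] > adj[i, j]) {
      adj[i, j] <- w[k]
      adj[j, i] <- w[k]
    }
  }
  structure(list(adj = adj, cap = cap), class = "similarity_graph")
}

#' Construct a similarity graph directly from a weight matrix
#'
#' @param adj symmetric non-negative matrix with dimnames.
#' @param cap weight cap used for the silhouette distance transform.
#' @return a `similarity_graph`.
#' @export
similarity_graph <- function(adj, cap = 200) {
  stopifnot(is.matrix(adj), !is.null(rownames(adj)),
            identical(rownames(adj), colnames(adj)))
  if (any(adj < 0) || any(!is.finite(adj))) stop("weights must be finite, >= 0")
  if (max(abs(adj - t(adj))) > 1e-12) stop("adjacency must be symmetric")
  diag(adj) <- 0
  structure(list(adj = adj, cap = cap), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity graph: ", nrow(x$adj), " nodes, ",
      sum(x$adj[upper.tri(x$adj)] > 0), " edges, cap ", x$cap, "\n", sep = "")
  invisible(x)
}

#' Markov clustering (MCL) of a similarity graph
#'
#' In-package implementation of the MCL process: the weighted adjacency
#' matrix (with self-loops set to each node's maximum incident weight)
#' is made column-stochastic, then expansion (matrix squaring) and
#' inflation (elementwise power `inflation`, column renormalization)
#' alternate, with entries below `floor` pruned, until the matrix is
#' (near-)idempotent. Clusters are the connected components of the
#' converged matrix's support. Deterministic for a fixed input ordering.
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation parameter (> 1).
#' @param floor numeric pruning floor (default 1e-6).
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the maximum column change
#'   (default 1e-8).
#' @return object of class `gene_clustering`: list with `labels` (named
#'   integer vector), `inflation`, `avg_silhouette` (NA until scored),
#'   `n_clusters`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation, floor = 1e-6, max_iter = 200L,
                        tol = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  A <- graph$adj
  n <- nrow(A)
  if (n == 0) stop("graph is empty")
  loops <- apply(A, 1L, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < floor] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
  support <- (M + t(M)) > floor
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  labels <- as.integer(comp)
  names(labels) <- rownames(A)
  structure(list(labels = labels, inflation = inflation,
                 avg_silhouette = NA_real_,
                 n_clusters = length(unique(labels)), iterations = it),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat("clustering: ", length(x$labels), " nodes in ", x$n_clusters,
      " clusters (inflation ", x$inflation, ")\n", sep = "")
  if (!is.na(x$avg_silhouette))
    cat("average silhouette width: ", round(x$avg_silhouette, 4), "\n",
        sep = "")
  invisible(x)
}

# distance used for silhouette scoring: d = 1 - w/cap, 1 for non-adjacent
silhouette_distance <- function(graph) {
  D <- 1 - graph$adj / graph$cap
  D[graph$adj == 0] <- 1
  diag(D) <- 0
  D
}

#' Average silhouette width of a clustering on a similarity graph
#'
#' Distances are the bounded transform `d(i, j) = 1 - w(i, j)/cap` with
#' `d = 1` for non-adjacent pairs. Returns `NA` when the clustering has
#' fewer than 2 clusters (silhouette undefined). Singleton clusters
#' contribute width 0.
#'
#' @param graph a `similarity_graph`.
#' @param clustering a `gene_clustering`.
#' @return scalar in \[-1, 1\], or NA.
#' @export
silhouette_score <- function(graph, clustering) {
  labels <- clustering$labels[rownames(graph$adj)]
  if (length(unique(labels)) < 2L) return(NA_real_)
  D <- silhouette_distance(graph)
  sil <- cluster::silhouette(as.integer(labels), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Select the MCL inflation parameter by averaged silhouette width
#'
#' Clusters the graph at each candidate inflation, scores each clustering
#' by its average silhouette width, and returns the clustering that
#' maximizes it. Ties go to the smallest inflation (coarsest clustering),
#' then input order.
#'
#' @param graph a `similarity_graph`.
#' @param candidates numeric vector of candidate inflations (>= 2 values).
#' @param ... passed to [mcl_cluster()].
#' @return list with `best` (a `gene_clustering` with `avg_silhouette`
#'   filled in) and `table` (data.frame: inflation, n_clusters,
#'   avg_silhouette).
#' @export
select_inflation <- function(graph, candidates = c(1.2, 1.4, 2, 4, 6), ...) {
  if (length(candidates) < 2L) stop("need at least 2 candidate inflations")
  runs <- lapply(candidates, function(I) {
    cl <- mcl_cluster(graph, I, ...)
    cl$avg_silhouette <- silhouette_score(graph, cl)
    cl
  })
  sbar <- vapply(runs, function(cl) cl$avg_silhouette, numeric(1))
  tab <- data.frame(inflation = candidates,
                    n_clusters = vapply(runs, function(cl)
                      cl$n_clusters, integer(1)),
                    avg_silhouette = sbar)
  if (all(is.na(sbar)))
    stop("silhouette undefined: every candidate yields a single cluster")
  ok <- which(!is.na(sbar))
  best_s <- max(sbar[ok])
  cand <- ok[sbar[ok] >= best_s - 1e-12]
  best <- cand[which.min(candidates[cand])]
  list(best = runs[[best]], table = tab)
}

#' Select loci that are (almost always) single copy across genomes
#'
#' Returns the loci whose fraction of genomes carrying exactly one copy
#' strictly exceeds `min_fraction` (the "over 95% single-copy" rule used
#' to pick species-tree markers).
#'
#' @param ortholog_table matrix or data.frame of copy counts, loci in
#'   rows, genomes in columns; absent means 0.
#' @param min_fraction strict lower bound on the single-copy fraction.
#' @return character vector of locus names.
#' @export
select_single_copy_loci <- function(ortholog_table, min_fraction = 0.95) {
  m <- as.matrix(ortholog_table)
  if (nrow(m) == 0 || ncol(m) == 0) {
    warning("empty ortholog table")
    return(character(0))
  }
  m[is.na(m)] <- 0
  frac <- rowMeans(m == 1)
  rownames(m)[frac > min_fraction]
}
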