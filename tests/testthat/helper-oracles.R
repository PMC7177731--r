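# Independent oracles used across the suite. These deliberately share no
# code with the package: plain loops, explicit enumeration, and external
# reference implementations where available.

# --- brute-force duplication/loss reconciliation -------------------------

# enumerate every valid mapping of gene-tree internal nodes to species
# nodes (each node mapped to an ancestor-or-self of the LCA of its
# children's images) and return the minimum duplication + loss cost
oracle_reconcile_cost <- function(gene_tree, species_tree, leaf_map) {
  sp <- species_tree
  ns_tip <- length(sp$tip.label)
  ns_all <- ns_tip + sp$Nnode
  sp_parent <- rep(NA_integer_, ns_all)
  sp_parent[sp$edge[, 2]] <- sp$edge[, 1]
  sp_depth <- rep(NA_integer_, ns_all)
  sp_depth[ns_tip + 1L] <- 0L
  while (anyNA(sp_depth)) {
    for (v in sp$edge[, 2])
      if (is.na(sp_depth[v]) && !is.na(sp_depth[sp_parent[v]]))
        sp_depth[v] <- sp_depth[sp_parent[v]] + 1L
  }
  ancestors_of <- function(v) {
    out <- v
    while (!is.na(sp_parent[v])) { v <- sp_parent[v]; out <- c(out, v) }
    out
  }
  in_subtree <- function(anc, v) anc %in% ancestors_of(v)
  sp_kids <- lapply(seq_len(ns_all), function(v) sp$edge[sp$edge[, 1] == v, 2])

  gt <- gene_tree
  ng_tip <- length(gt$tip.label)
  ng_all <- ng_tip + gt$Nnode
  g_kids <- lapply(seq_len(ng_all), function(v) gt$edge[gt$edge[, 1] == v, 2])
  sp_of <- setNames(leaf_map$species, leaf_map$leaf)
  M_leaf <- match(sp_of[gt$tip.label], sp$tip.label)

  # postorder list of internal gene nodes
  g_order <- integer(0)
  visit <- function(v) {
    for (c in g_kids[[v]]) if (c > ng_tip) visit(c)
    g_order <<- c(g_order, v)
  }
  visit(ng_tip + 1L)

  cost_of_mapping <- function(M) {
    D <- 0L; L <- 0L
    is_dup <- rep(FALSE, ng_all)
    for (v in g_order) {
      ch <- g_kids[[v]]
      # speciation iff children images fall in distinct child subtrees
      # of M(v)
      ok_spec <- FALSE
      kids_v <- sp_kids[[M[v]]]
      if (length(kids_v) == 2L &&
          M[ch[1]] != M[v] && M[ch[2]] != M[v]) {
        s1 <- in_subtree(kids_v[1], M[ch[1]])
        s2 <- in_subtree(kids_v[2], M[ch[2]])
        s1b <- in_subtree(kids_v[2], M[ch[1]])
        s2b <- in_subtree(kids_v[1], M[ch[2]])
        ok_spec <- (s1 && s2) || (s1b && s2b)
      }
      if (!ok_spec) { is_dup[v] <- TRUE; D <- D + 1L }
    }
    for (k in seq_len(nrow(gt$edge))) {
      p <- gt$edge[k, 1]; c1 <- gt$edge[k, 2]
      gap <- sp_depth[M[c1]] - sp_depth[M[p]]
      L <- L + gap - 1L + is_dup[p] + (gap == 0L && !is_dup[p])
      # gap==0 with speciation parent is impossible for valid mappings
    }
    D + L
  }

  best <- Inf
  M <- integer(ng_all)
  M[seq_len(ng_tip)] <- M_leaf
  recurse <- function(i) {
    if (i > length(g_order)) {
      best <<- min(best, cost_of_mapping(M))
      return(invisible(NULL))
    }
    v <- g_order[i]
    ch <- g_kids[[v]]
    # lca of children images
    a <- M[ch[1]]; b <- M[ch[2]]
    while (a != b) {
      if (sp_depth[a] < sp_depth[b]) b <- sp_parent[b]
      else if (sp_depth[b] < sp_depth[a]) a <- sp_parent[a]
      else { a <- sp_parent[a]; b <- sp_parent[b] }
    }
    for (cand in ancestors_of(a)) {
      M[v] <<- cand
      recurse(i + 1L)
    }
  }
  # g_order is postorder so children are assigned before parents
  recurse(1L)
  best
}

# --- NG86 path-enumeration oracle ----------------------------------------

oracle_ng86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  syn_frac <- function(codon) {
    chars <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) for (b in nt) {
      if (b == chars[pos]) next
      alt <- chars; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
    s
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  path_counts <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    diff <- which(ca != cb)
    if (length(diff) == 0) return(c(0, 0))
    walk <- function(ord, allow) {
      cur <- ca; sd <- 0; nd <- 0
      for (pos in ord) {
        prev <- paste(cur, collapse = "")
        cur[pos] <- cb[pos]
        nxt <- paste(cur, collapse = "")
        if (!allow && gc[[nxt]] == "*") return(NULL)
        if (gc[[prev]] == gc[[nxt]] && gc[[nxt]] != "*") sd <- sd + 1
        else nd <- nd + 1
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null),
                  lapply(all_orders(diff), walk, allow = FALSE))
    if (length(res) == 0)
      res <- lapply(all_orders(diff), walk, allow = TRUE)
    colMeans(do.call(rbind, res))
  }
  S <- (sum(vapply(c1, syn_frac, 0)) + sum(vapply(c2, syn_frac, 0))) / 2
  N <- 3 * length(c1) - S
  sdnd <- rowSums(vapply(seq_along(c1),
                         function(k) path_counts(c1[k], c2[k]), numeric(2)))
  list(N = N, S = S, Nd = sdnd[2], Sd = sdnd[1])
}

# --- misc fixtures -------------------------------------------------------

# random in-frame stop-free coding sequence
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# planted k-block similarity graph
planted_block_graph <- function(n_blocks = 3, block_size = 5,
                                intra_w = 200, inter_w = 5, cap = 200,
                                seed = 1) {
  set.seed(seed)
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  ids <- paste0("n", sample(n))    # scrambled labels
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- if (blocks[i] == blocks[j]) intra_w else inter_w
    adj[i, j] <- adj[j, i] <- w
  }
  list(graph = similarity_graph(adj, cap = cap),
       truth = setNames(blocks, ids))
}

# do two labelings define the same partition?
same_partition <- function(a, b) {
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# random additive distance matrix from a random tree
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 1))
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}
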