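# Gene-tree / species-tree reconciliation under a duplication/loss
# parsimony model (no transfers), reconstruction selection among
# candidate gene trees, and duplication-timing classification.

# topological node depths (edges counted from the root); works without
# branch lengths
node_depths_topo <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- rep(NA_integer_, n_all)
  depth[length(tree$tip.label) + 1L] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    can <- todo[!is.na(depth[parent[todo]])]
    if (length(can) == 0) stop("disconnected tree")
    depth[can] <- depth[parent[can]] + 1L
  }
  depth
}

# index helpers over a rooted species tree
species_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  tree <- if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    label_internal_nodes(tree) else tree
  n_all <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- node_depths_topo(tree)
  kids <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge)))
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  list(tree = tree, n_tip = n_tip, parent = parent, depth = depth,
       kids = kids, labels = node_labels(tree), root = n_tip + 1L)
}

species_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else if (idx$depth[b] < idx$depth[a]) a <- idx$parent[a]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

# is `anc` an ancestor of (or equal to) `v`?
species_is_ancestor <- function(idx, anc, v) {
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- idx$parent[v]
  }
  FALSE
}

#' LCA reconciliation of a gene tree against a species tree
#'
#' Maps every gene-tree node to the species-tree last common ancestor of
#' its descendants' species (the LCA mapping), labels each internal node
#' as a speciation or a duplication (duplication iff the node maps to the
#' same species node as one of its children), and counts losses from
#' depth gaps along the mapped paths. For rooted binary inputs this is
#' the unique minimum duplication+loss reconciliation.
#'
#' Loss counting per gene edge (parent p -> child c), with `k` the
#' species-tree depth difference between M(c) and M(p): a speciation
#' parent contributes `k - 1` losses (one per off-path branch strictly
#' inside the path), a duplication parent contributes `k` (the copy also
#' misses the off-path branch at M(p) itself). Worked example: species
#' tree ((A,B),C), gene tree ((A1,B1),C1) with species D absent would
#' need no events; the same gene tree against ((A,B),(C,D)) maps its
#' root to the species root with a speciation, and the edge down to C1
#' skips the C-D ancestor, losing the D branch: D = 0, L = 1.
#'
#' @param gene_tree rooted binary `ape::phylo`; internal nodes are
#'   auto-labeled `n<k>` when unlabeled.
#' @param species_tree rooted binary `ape::phylo`.
#' @param leaf_map data.frame with columns `leaf` (gene tip label) and
#'   `species` (species tip label), total over gene tips.
#' @param c_dup,c_loss event costs (defaults 1).
#' @return object of class `reconciliation`: list with `events`
#'   (data.frame: node, species_node, event), `losses` (data.frame:
#'   species_branch, count), `D`, `L`, `cost`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map,
                          c_dup = 1, c_loss = 1) {
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree))
    stop("both trees must be rooted; see root_with_outgroup()")
  if (!ape::is.binary(gene_tree)) gene_tree <- resolve_polytomies(gene_tree)
  if (!ape::is.binary(species_tree)) stop("species tree must be binary")
  idx <- species_index(species_tree)
  gt <- gene_tree
  g_tip <- length(gt$tip.label)
  if (is.null(gt$node.label) || any(!nzchar(gt$node.label)))
    gt$node.label <- paste0("n", seq_len(gt$Nnode))
  g_labels <- c(gt$tip.label, gt$node.label)

  sp_of <- stats::setNames(leaf_map$species, leaf_map$leaf)
  missing_map <- setdiff(gt$tip.label, names(sp_of))
  if (length(missing_map) > 0)
    stop("leaf map missing gene tips: ", paste(missing_map, collapse = ", "))
  bad_sp <- setdiff(unique(leaf_map$species), species_tree$tip.label)
  if (length(bad_sp) > 0)
    stop("species not in species tree: ", paste(bad_sp, collapse = ", "))

  n_all <- g_tip + gt$Nnode
  gkids <- vector("list", n_all)
  for (k in seq_len(nrow(gt$edge)))
    gkids[[gt$edge[k, 1]]] <- c(gkids[[gt$edge[k, 1]]], gt$edge[k, 2])

  M <- integer(n_all)
  for (i in seq_len(g_tip))
    M[i] <- match(sp_of[[gt$tip.label[i]]], idx$tree$tip.label)
  gdepth <- node_depths_topo(gt)
  post <- order(gdepth, decreasing = TRUE)
  post <- post[post > g_tip]
  for (v in post) {
    ch <- gkids[[v]]
    m <- M[ch[1]]
    for (c2 in ch[-1]) m <- species_lca(idx, m, M[c2])
    M[v] <- m
  }

  is_dup <- logical(n_all)
  for (v in which(seq_len(n_all) > g_tip))
    is_dup[v] <- any(M[gkids[[v]]] == M[v])

  # losses along each gene edge
  loss_count <- stats::setNames(numeric(length(idx$labels)), idx$labels)
  for (k in seq_len(nrow(gt$edge))) {
    p <- gt$edge[k, 1]; c1 <- gt$edge[k, 2]
    top <- M[p]; bot <- M[c1]
    start_at_top <- is_dup[p]   # duplication copies re-enter at M(p) itself
    v <- bot
    path <- integer(0)
    while (v != top) { path <- c(path, v); v <- idx$parent[v] }
    # path holds nodes below top down to bot (bot first)
    nodes_passed <- if (length(path) == 0) integer(0) else
      if (start_at_top) c(path[-1], top) else path[-1]
    for (s in nodes_passed) {
      on_path_child <- if (s == top) path[length(path)] else
        path[which(path == s) - 1L]
      off <- setdiff(idx$kids[[s]], on_path_child)
      for (o in off)
        loss_count[idx$labels[o]] <- loss_count[idx$labels[o]] + 1
    }
  }

  internal <- which(seq_len(n_all) > g_tip)
  events <- data.frame(node = g_labels[internal],
                       species_node = idx$labels[M[internal]],
                       event = ifelse(is_dup[internal], "duplication",
                                      "speciation"))
  losses <- data.frame(species_branch = names(loss_count),
                       count = as.numeric(loss_count))
  losses <- losses[losses$count > 0, , drop = FALSE]
  rownames(losses) <- NULL
  D <- sum(is_dup)
  L <- sum(loss_count)
  structure(list(events = events, losses = losses, D = D, L = L,
                 cost = c_dup * D + c_loss * L, c_dup = c_dup,
                 c_loss = c_loss, gene_tree = gt,
                 species_tree = idx$tree, leaf_map = leaf_map,
                 mapping = stats::setNames(idx$labels[M], g_labels)),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation: D = ", x$D, ", L = ", x$L, ", cost = ", x$cost,
      "\n", sep = "")
  invisible(x)
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved into caterpillars in the lexicographic
#' order of each child subtree's smallest leaf label, with zero-length
#' branches, and the tree is flagged via attribute `resolved_polytomies`.
#'
#' @param tree an `ape::phylo`.
#' @return binary `ape::phylo`.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree2 <- ape::makeNodeLabel(tree, method = "number", prefix = "poly")
  # rotate children into deterministic order, then resolve
  tree2 <- ape::rotateConstr(tree2, sort(tree2$tip.label))
  out <- ape::multi2di(tree2, random = FALSE)
  out$edge.length[is.na(out$edge.length)] <- 0
  attr(out, "resolved_polytomies") <- TRUE
  out
}

#' Pick the minimum-cost reconciliation among candidates
#'
#' Ties are broken by fewer duplications, then input order.
#'
#' @param candidates list of `reconciliation` objects for the same
#'   species tree.
#' @return integer index of the selected candidate.
#' @export
choose_reconstruction <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate reconstructions")
  costs <- vapply(candidates, function(r) r$cost, numeric(1))
  dups <- vapply(candidates, function(r) r$D, numeric(1))
  best <- which(costs == min(costs))
  best <- best[dups[best] == min(dups[best])]
  best[1]
}

#' Classify duplication timing against the species tree
#'
#' Each duplication is labeled with the species-tree branch its mapping
#' lies on: a leaf branch is "lineage-specific"; a named internal branch
#' (via `clade_labels`) gets its name (e.g. "ancestral-legume");
#' otherwise the raw branch label is reported. Tandem flags (from
#' synteny, or a simulation event log) are propagated. Optionally, only
#' duplications whose subtending gene-tree branch reaches a support
#' threshold are reported.
#'
#' @param result a `reconciliation`.
#' @param clade_labels optional named character vector: species branch
#'   label -> clade name.
#' @param tandem_flags optional character vector of gene-node labels
#'   known to be tandem duplications.
#' @param support optional named numeric vector: gene node label ->
#'   percent support.
#' @param min_support support threshold applied when `support` is given
#'   (default 90).
#' @return data.frame with columns node, species_branch, label, tandem.
#' @export
classify_duplication_timing <- function(result, clade_labels = NULL,
                                        tandem_flags = NULL,
                                        support = NULL, min_support = 90) {
  stopifnot(inherits(result, "reconciliation"))
  ev <- result$events[result$events$event == "duplication", , drop = FALSE]
  if (!is.null(support)) {
    s <- support[ev$node]
    ev <- ev[!is.na(s) & s >= min_support, , drop = FALSE]
  }
  sp_tips <- result$species_tree$tip.label
  label <- vapply(ev$species_node, function(b) {
    if (!is.null(clade_labels) && b %in% names(clade_labels))
      return(clade_labels[[b]])
    if (b %in% sp_tips) return("lineage-specific")
    b
  }, character(1))
  data.frame(node = ev$node, species_branch = ev$species_node,
             label = label,
             tandem = ev$node %in% tandem_flags)
}
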