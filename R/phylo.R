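# Desk-scale tree building: pairwise-deletion nucleotide distances from
# codon alignments, neighbor-joining (via ape), outgroup rooting and
# nonparametric bootstrap support over codon columns. Externally computed
# Newick trees are accepted anywhere a tree is an input.

# nucleotide character matrix of an alignment; NA for gaps/ambiguity
nt_matrix <- function(aln) {
  s <- aln_to_strings(aln)
  m <- do.call(rbind, strsplit(s, ""))
  m[!(m %in% c("A", "C", "G", "T"))] <- NA_character_
  rownames(m) <- rownames(aln)
  m
}

#' Pairwise distances from a codon alignment
#'
#' Pairwise-deletion distances at the nucleotide level: sites where
#' either sequence has a gap or an ambiguous base are skipped for that
#' pair. `p_distance` is the raw mismatch proportion; `jc_nucleotide`
#' applies the Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)`.
#' Saturated pairs (p >= 0.75 under JC) receive the ceiling distance and
#' are flagged.
#'
#' @param aln a [codon_aln] with >= 2 sequences.
#' @param model `"p_distance"` or `"jc_nucleotide"`.
#' @param min_overlap minimum ungapped sites shared by a pair (default 30).
#' @param ceiling distance assigned to saturated pairs (default 5.0).
#' @return symmetric matrix; attribute `saturated` holds flagged pairs.
#' @export
pairwise_distance <- function(aln, model = c("jc_nucleotide", "p_distance"),
                              min_overlap = 30L, ceiling = 5.0) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_aln"))
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  m <- nt_matrix(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  sat <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      overlap <- sum(ok)
      if (overlap < min_overlap)
        stop("pair ", rownames(aln)[i], "/", rownames(aln)[j],
             " shares only ", overlap, " ungapped sites")
      p <- sum(m[i, ok] != m[j, ok]) / overlap
      d <- if (model == "p_distance") p else if (p >= 0.75) {
        sat <- c(sat, paste(rownames(aln)[i], rownames(aln)[j], sep = "|"))
        ceiling
      } else -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining gene tree
#'
#' Standard Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Negative branch lengths are clamped to zero with a warning.
#'
#' @param D symmetric distance matrix over >= 3 taxa.
#' @return unrooted `ape::phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Root a tree on a declared outgroup
#'
#' Places the root on the branch subtending the (monophyletic) outgroup;
#' optionally prunes the outgroup afterwards, the usual preparation
#' before gene-tree/species-tree reconciliation.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup_labels character vector of outgroup tip labels.
#' @param prune drop the outgroup tips after rooting (default FALSE).
#' @return rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_labels, prune = FALSE) {
  missing_tips <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("outgroup tips not in tree: ", paste(missing_tips, collapse = ", "))
  if (length(outgroup_labels) < length(tree$tip.label) - 1L &&
      !ape::is.monophyletic(tree, outgroup_labels))
    stop("outgroup is not monophyletic; conflicting leaves among: ",
         paste(outgroup_labels, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE)
  if (prune) {
    if (length(outgroup_labels) >= length(tree$tip.label) - 1L)
      stop("pruning the outgroup would leave fewer than 2 tips")
    rooted <- ape::drop.tip(rooted, outgroup_labels)
  }
  rooted
}

#' Bootstrap support for NJ trees by codon-column resampling
#'
#' Resamples codon columns with replacement, rebuilds the NJ tree for
#' each replicate and annotates each internal branch of the full-data
#' tree with the percentage of replicates containing that bipartition.
#'
#' @param aln a [codon_aln].
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed (fixed seed gives identical supports).
#' @param model distance model passed to [pairwise_distance()].
#' @return the NJ tree with `node.label` set to integer percent support.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              model = "jc_nucleotide") {
  stopifnot(inherits(aln, "codon_aln"), n_replicates >= 1L)
  set.seed(seed)
  base <- nj_tree(pairwise_distance(aln, model = model))
  L <- ncol(aln)
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- suppressWarnings(
      nj_tree(pairwise_distance(aln[, cols], model = model)))
  }
  counts <- ape::prop.clades(base, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$node.label <- as.character(round(100 * counts / n_replicates))
  base
}
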