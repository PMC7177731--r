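# Synthetic-data generators: species trees with whole-genome duplications,
# gene families evolving by birth-death duplication/loss, codon alignments
# under site- and branch-specific dN/dS, and droplet digital PCR assays.
# Ground-truth event logs make every downstream stage testable.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash so that one master seed drives every
#' stochastic operation of a run while sub-operations stay independent.
#' Result is always in \[1, 2^31 - 2\].
#'
#' @param master integer master seed.
#' @param tag character tag naming the sub-operation.
#' @return integer seed.
#' @export
derive_seed <- function(master, tag = "") {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' Label the internal nodes of a tree
#'
#' Assigns stable labels to unlabeled internal nodes: the root becomes
#' `"root"` and other internal nodes `"N<k>"` (preorder). Existing
#' non-empty labels are kept.
#'
#' @param tree an `ape::phylo` object.
#' @param prefix label prefix for non-root internal nodes.
#' @return the tree with `node.label` set.
#' @export
label_internal_nodes <- function(tree, prefix = "N") {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  lab[is.na(lab)] <- ""
  auto <- c("root", paste0(prefix, seq_len(max(n_node - 1L, 0L)) + 1L))
  empty <- !nzchar(lab)
  lab[empty] <- auto[seq_len(n_node)][empty]
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("tree labels are not unique after labeling internal nodes")
  tree$node.label <- lab
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' Species tree specification with whole-genome duplication events
#'
#' Bundles a rooted binary species tree (branch lengths in arbitrary time
#' units) with a list of whole-genome duplication (WGD) events. Each WGD
#' sits on a branch, identified by the label of the node below it (the
#' root label denotes the stem above the root), at a relative position
#' along the branch, and retains each extra gene copy independently with a
#' retention probability. Multiplicity 2 is a duplication, 3 a
#' triplication (both are observed in genistoid legumes).
#'
#' @param newick Newick string or `phylo` object; rooted, binary, with
#'   non-negative branch lengths.
#' @param wgd_events optional data.frame with columns `branch` (node
#'   label), `time_frac` in (0,1), `retention` in \[0,1\],
#'   `multiplicity` in \{2, 3\}.
#' @return object of class `species_tree_spec`.
#' @export
species_tree_spec <- function(newick, wgd_events = NULL) {
  tree <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse species tree")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  n_tip <- length(tree$tip.label)
  if (n_tip > 1L && !ape::is.binary(tree)) stop("species tree must be binary")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label)) stop("taxon labels must be unique")
  tree <- label_internal_nodes(tree)
  if (!is.null(wgd_events)) {
    wgd_events <- as.data.frame(wgd_events)
    need <- c("branch", "time_frac", "retention", "multiplicity")
    if (!all(need %in% names(wgd_events)))
      stop("wgd_events needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(wgd_events$branch, node_labels(tree))
    if (length(bad) > 0)
      stop("wgd branch not in tree: ", paste(bad, collapse = ", "))
    if (any(wgd_events$retention < 0 | wgd_events$retention > 1))
      stop("retention probability must be in [0, 1]")
    if (any(wgd_events$time_frac <= 0 | wgd_events$time_frac >= 1))
      stop("time_frac must be in (0, 1)")
    if (!all(wgd_events$multiplicity %in% c(2L, 3L)))
      stop("WGD multiplicity must be 2 or 3")
  }
  structure(list(tree = tree, wgd = wgd_events), class = "species_tree_spec")
}

#' Gene family birth-death simulation parameters
#'
#' @param birth duplication rate (events per lineage per unit time).
#' @param death loss rate (events per lineage per unit time).
#' @param tandem_fraction fraction of duplications labeled tandem (the
#'   label is ground-truth metadata; no coordinates are simulated).
#' @param seed integer RNG seed.
#' @return object of class `family_sim_params`.
#' @export
family_sim_params <- function(birth = 0, death = 0, tandem_fraction = 0,
                              seed = 1L) {
  if (birth < 0 || death < 0) stop("rates must be >= 0")
  if (tandem_fraction < 0 || tandem_fraction > 1)
    stop("tandem_fraction must be in [0, 1]")
  structure(list(birth = birth, death = death,
                 tandem_fraction = tandem_fraction, seed = as.integer(seed)),
            class = "family_sim_params")
}

#' Simulate a gene family along a species tree
#'
#' One gene lineage enters at the species-tree stem and evolves by a
#' Gillespie birth-death process (duplication rate `birth`, loss rate
#' `death`) along every species branch. WGD events apply instantaneously
#' to all lineages alive at the event point; each extra copy is retained
#' independently with the event's retention probability. Speciation copies
#' every lineage into both descendant branches.
#'
#' @param species a [species_tree_spec()].
#' @param params a [family_sim_params()].
#' @return list with elements `tree` (an `ape::phylo` with internal nodes
#'   labeled by simulation node ids, or `NULL` if fewer than 2 copies
#'   survive), `leaf_map` (data.frame: leaf, node_id, species), `events`
#'   (data.frame: event, node_id, species_branch, time) and `n_leaves`.
#' @export
simulate_gene_tree <- function(species, params) {
  stopifnot(inherits(species, "species_tree_spec"),
            inherits(params, "family_sim_params"))
  set.seed(params$seed)
  tree <- species$tree
  n_tip <- length(tree$tip.label)
  labs <- node_labels(tree)
  root <- n_tip + 1L
  times <- ape::node.depth.edgelength(tree)
  kids <- vector("list", n_tip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge)))
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  edge_len <- numeric(n_tip + tree$Nnode)
  edge_len[tree$edge[, 2]] <- tree$edge.length

  # mutable simulation state
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$parent <- integer(0)
  st$time <- numeric(0)
  st$type <- character(0)
  st$events <- list()
  new_node <- function(parent, time, type) {
    st$n <- st$n + 1L
    st$parent[st$n] <- parent
    st$time[st$n] <- time
    st$type[st$n] <- type
    st$n
  }
  log_event <- function(event, node, branch, time) {
    st$events[[length(st$events) + 1L]] <-
      data.frame(event = event, node_id = paste0("g", node),
                 species_branch = branch, time = time)
  }

  birth <- params$birth; death <- params$death
  total <- birth + death

  gillespie <- function(lineages, t0, t1, branch_lab) {
    if (total == 0 || t1 <= t0) return(lineages)
    out <- integer(0)
    stack <- lapply(lineages, function(l) c(l, t0))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lin <- as.integer(cur[1]); t <- cur[2]
      repeat {
        wait <- stats::rexp(1, total)
        if (t + wait >= t1) { out <- c(out, lin); break }
        t <- t + wait
        if (stats::runif(1) < birth / total) {
          tandem <- params$tandem_fraction > 0 &&
            stats::runif(1) < params$tandem_fraction
          nid <- new_node(lin, t, "dup")
          log_event(if (tandem) "tandem_duplication" else "duplication",
                    nid, branch_lab, t)
          stack[[length(stack) + 1L]] <- c(nid, t)
          lin <- nid   # continue the other daughter in place
        } else {
          log_event("loss", lin, branch_lab, t)
          break
        }
      }
    }
    out
  }

  apply_wgd <- function(lineages, w, t, branch_lab) {
    out <- integer(0)
    for (lin in lineages) {
      extras <- sum(stats::runif(w$multiplicity - 1L) < w$retention)
      cur <- lin
      if (extras > 0) {
        for (k in seq_len(extras)) {
          nid <- new_node(cur, t, "dup")
          log_event("wgd_retention", nid, branch_lab, t)
          out <- c(out, nid)    # the extra copy
          cur <- nid            # chain further retained copies below
        }
      }
      out <- c(out, cur)        # the continuing original
    }
    out
  }

  wgd_for <- function(lab) {
    if (is.null(species$wgd)) return(NULL)
    w <- species$wgd[species$wgd$branch == lab, , drop = FALSE]
    if (nrow(w) == 0) NULL else w[order(w$time_frac), , drop = FALSE]
  }

  evolve_branch <- function(lineages, sp_child) {
    lab <- labs[sp_child]
    t1 <- times[sp_child]
    t0 <- t1 - edge_len[sp_child]
    w <- wgd_for(lab)
    tcur <- t0
    if (!is.null(w)) {
      for (k in seq_len(nrow(w))) {
        tw <- t0 + w$time_frac[k] * (t1 - t0)
        lineages <- gillespie(lineages, tcur, tw, lab)
        lineages <- apply_wgd(lineages, w[k, ], tw, lab)
        tcur <- tw
      }
    }
    lineages <- gillespie(lineages, tcur, t1, lab)
    if (length(lineages) == 0) return(invisible(NULL))
    at_node(lineages, sp_child)
  }

  at_node <- function(lineages, sp_node) {
    ch <- kids[[sp_node]]
    if (length(ch) == 0) {                    # species leaf: gene copies
      for (lin in lineages) new_node(lin, times[sp_node], "leaf")
      ids <- seq(st$n - length(lineages) + 1L, st$n)
      st$leaf_species <- rbind(st$leaf_species,
                               data.frame(node = ids, species = labs[sp_node]))
      return(invisible(NULL))
    }
    if (length(ch) == 1L) {                   # degenerate (single-taxon) tree
      evolve_branch(lineages, ch)
      return(invisible(NULL))
    }
    specs <- integer(0)
    for (lin in lineages) {
      v <- new_node(lin, times[sp_node], "spec")
      log_event("speciation", v, labs[sp_node], times[sp_node])
      specs <- c(specs, v)
    }
    for (b in ch) evolve_branch(specs, b)
    invisible(NULL)
  }

  st$leaf_species <- data.frame(node = integer(0), species = character(0))
  g_root <- new_node(NA_integer_, times[root], "root")
  lineages <- g_root
  w_stem <- wgd_for(labs[root])
  if (!is.null(w_stem)) {
    for (k in seq_len(nrow(w_stem)))
      lineages <- apply_wgd(lineages, w_stem[k, ], times[root], labs[root])
  }
  at_node(lineages, root)

  events <- if (length(st$events) > 0) do.call(rbind, st$events) else
    data.frame(event = character(0), node_id = character(0),
               species_branch = character(0), time = numeric(0))

  leaves <- st$leaf_species
  n_leaves <- nrow(leaves)
  if (n_leaves == 0L) {
    return(list(tree = NULL, leaf_map = data.frame(
      leaf = character(0), node_id = character(0), species = character(0)),
      events = events, n_leaves = 0L))
  }
  # leaf labels: <species>_<k>
  leaves$leaf <- paste0(leaves$species, "_",
                        stats::ave(seq_len(n_leaves), leaves$species,
                                   FUN = seq_along))
  leaf_lab <- stats::setNames(leaves$leaf, leaves$node)

  # prune extinct subtrees, collapse unary nodes, emit Newick
  children <- vector("list", st$n)
  for (i in seq_len(st$n)) {
    p <- st$parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  alive <- logical(st$n)
  mark <- function(i) {
    if (st$type[i] == "leaf") { alive[i] <<- TRUE; return(TRUE) }
    any_alive <- FALSE
    for (c in children[[i]]) if (mark(c)) any_alive <- TRUE
    alive[i] <<- any_alive
    any_alive
  }
  mark(g_root)

  nw <- function(i) {
    ch <- children[[i]]
    ch <- ch[alive[ch]]
    if (st$type[i] == "leaf")
      return(list(str = leaf_lab[[as.character(i)]], time = st$time[i]))
    if (length(ch) == 1L) return(nw(ch))
    parts <- lapply(ch, nw)
    body <- paste(vapply(parts, function(p)
      sprintf("%s:%.10g", p$str, p$time - st$time[i]), character(1)),
      collapse = ",")
    list(str = sprintf("(%s)g%d", body, i), time = st$time[i])
  }

  if (n_leaves == 1L) {
    ltree <- NULL
  } else {
    top <- nw(g_root)
    ltree <- ape::read.tree(text = paste0(top$str, ";"))
  }
  list(tree = ltree,
       leaf_map = data.frame(leaf = leaves$leaf,
                             node_id = paste0("g", leaves$node),
                             species = leaves$species),
       events = events, n_leaves = n_leaves)
}

#' Check lineage-count bookkeeping of a simulated family
#'
#' For every species leaf, the number of surviving gene copies must equal
#' 1 + (duplications on the root path) - (losses on the root path), where
#' the path runs from the stem to that leaf. Returns TRUE invisibly or
#' stops with a message.
#'
#' @param sim result of [simulate_gene_tree()].
#' @param species the [species_tree_spec()] used.
#' @return TRUE (invisibly) if the identity holds for every species leaf.
#' @export
check_event_conservation <- function(sim, species) {
  tree <- species$tree
  labs <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (i in seq_len(n_tip)) {
    path <- labs[i]
    v <- i
    while (v != n_tip + 1L) { v <- parent_of[v]; path <- c(path, labs[v]) }
    ev <- sim$events[sim$events$species_branch %in% path, , drop = FALSE]
    dups <- sum(ev$event %in% c("duplication", "tandem_duplication",
                                "wgd_retention"))
    losses <- sum(ev$event == "loss")
    observed <- sum(sim$leaf_map$species == labs[i])
    expected <- 1L + dups - losses
    if (observed != expected)
      stop(sprintf("leaf %s: %d copies observed, %d expected from event log",
                   labs[i], observed, expected))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Codon alignment simulation

#' Codon simulation parameters (site classes and branch-specific dN/dS)
#'
#' Sites fall into three classes: class 0 under purifying selection
#' (`omega0` in (0, 1\]), class 1 neutral (`omega1 = 1`), and class 2
#' under positive selection (`omega2 >= 1`) on the designated foreground
#' branches. On background branches class-2 sites evolve neutrally, which
#' is the behaviour the branch-site inference model assumes.
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param pi codon frequencies (61-vector summing to 1); default equal.
#' @param props proportions of site classes 0, 1, 2 (sum to 1).
#' @param omegas dN/dS for the three classes; `omegas[2]` must be 1.
#' @param foreground character vector of branch ids (labels of the nodes
#'   below the foreground branches).
#' @param n_codons alignment length in codons.
#' @param seed integer RNG seed.
#' @return object of class `codon_sim_params`.
#' @export
codon_sim_params <- function(kappa = 2, pi = NULL, props = c(0.5, 0.5, 0),
                             omegas = c(0.1, 1, 1), foreground = character(0),
                             n_codons = 300L, seed = 1L) {
  if (is.null(pi)) pi <- equal_codon_freqs()
  if (kappa <= 0) stop("kappa must be > 0")
  if (length(pi) != 61L || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 61 frequencies summing to 1")
  if (length(props) != 3L || abs(sum(props) - 1) > 1e-9)
    stop("props must be 3 proportions summing to 1")
  if (omegas[1] <= 0 || omegas[1] > 1) stop("omega0 must be in (0, 1]")
  if (omegas[2] != 1) stop("omega1 is fixed at 1")
  if (omegas[3] < 1) stop("omega2 must be >= 1")
  structure(list(kappa = kappa, pi = pi, props = props, omegas = omegas,
                 foreground = foreground, n_codons = as.integer(n_codons),
                 seed = as.integer(seed)),
            class = "codon_sim_params")
}

#' Simulate a gap-free codon alignment along a gene tree
#'
#' Evolves codon sequences down the tree under the GY94-style model with
#' the site classes of [codon_sim_params()]. Branch lengths are expected
#' substitutions per codon site under the background site-class mixture.
#' Stop codons cannot be generated (61-state space).
#'
#' @param gene_tree an `ape::phylo` with non-negative branch lengths, or a
#'   single sequence id (character scalar) for a one-sequence "alignment".
#' @param params a [codon_sim_params()].
#' @return a [codon_aln] with attributes `site_classes` (integer 0/1/2 per
#'   column) and `params`.
#' @export
simulate_codon_alignment <- function(gene_tree, params) {
  stopifnot(inherits(params, "codon_sim_params"))
  set.seed(params$seed)
  tab <- codon_tables()
  pi <- params$pi
  L <- params$n_codons
  classes <- sample.int(3L, L, replace = TRUE, prob = params$props) - 1L

  if (is.character(gene_tree) && length(gene_tree) == 1L) {
    s <- sample.int(61L, L, replace = TRUE, prob = pi)
    m <- matrix(tab$codons[s], nrow = 1L, dimnames = list(gene_tree, NULL))
    out <- codon_aln(m)
    attr(out, "site_classes") <- classes
    attr(out, "params") <- params
    return(out)
  }
  tree <- gene_tree
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("gene tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths not allowed")
  n_tip <- length(tree$tip.label)
  labs <- node_labels(tree)
  if (is.null(tree$node.label)) labs <- c(tree$tip.label, rep("", tree$Nnode))

  # background mixture fixes the time scale: class-2 sites are neutral there
  bg_omegas <- c(params$omegas[1], 1, 1)
  scale <- codon_mixture_scale(params$kappa, pi, bg_omegas, params$props)

  dec <- lapply(unique(c(bg_omegas, params$omegas[3])), function(w)
    codon_eigen(gy94_rate_matrix(params$kappa, w, pi) / scale, pi))
  names(dec) <- as.character(unique(c(bg_omegas, params$omegas[3])))

  states <- matrix(NA_integer_, n_tip + tree$Nnode, L)
  root <- n_tip + 1L
  states[root, ] <- sample.int(61L, L, replace = TRUE, prob = pi)
  ord <- order(node_depths_topo(tree)[tree$edge[, 2]])
  for (k in ord) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    t <- tree$edge.length[k]
    fg <- labs[child] %in% params$foreground
    omg <- if (fg) params$omegas else bg_omegas
    for (cl in 0:2) {
      sites <- which(classes == cl)
      if (length(sites) == 0) next
      P <- codon_pmat(dec[[as.character(omg[cl + 1L])]], t)
      ps <- states[par, sites]
      for (s in unique(ps)) {
        idx <- sites[ps == s]
        states[child, idx] <- sample.int(61L, length(idx), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  m <- matrix(tab$codons[states[seq_len(n_tip), , drop = FALSE]],
              nrow = n_tip, dimnames = list(tree$tip.label, NULL))
  out <- codon_aln(m)
  attr(out, "site_classes") <- classes
  attr(out, "params") <- params
  out
}

# ---------------------------------------------------------------------------
# Droplet assay simulation

#' Simulate a droplet digital PCR assay
#'
#' Template molecules partition into droplets independently, so the copy
#' number per droplet is Poisson with mean `lambda` and a droplet is
#' positive with probability `1 - exp(-lambda)`.
#'
#' @param n_droplets number of accepted droplets (>= 1).
#' @param lambda mean template copies per droplet (>= 0).
#' @param seed integer RNG seed.
#' @param target label for the amplicon.
#' @return a [droplet_assay()].
#' @export
simulate_droplets <- function(n_droplets, lambda, seed = 1L,
                              target = "target") {
  if (n_droplets < 1) stop("n_droplets must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  set.seed(seed)
  p_pos <- 1 - exp(-lambda)
  n_pos <- stats::rbinom(1L, as.integer(n_droplets), p_pos)
  droplet_assay(n_total = as.integer(n_droplets),
                n_negative = as.integer(n_droplets) - n_pos,
                target = target)
}

# ---------------------------------------------------------------------------
# Family bundle writer

#' Exon-count presets for emitted gene structures
#'
#' Dominant exon counts observed for the gene families this package
#' targets: cytosolic glutamine synthetase (GS1) 12 exons, plastid GS2
#' 13, plant-type PEPC 10 and bacterial-type PEPC 20.
#'
#' @param preset one of "GS1", "GS2", "PEPC", "PEPC-btpc".
#' @return integer modal exon count.
#' @export
exon_count_preset <- function(preset = c("GS1", "GS2", "PEPC", "PEPC-btpc")) {
  preset <- match.arg(preset)
  c(GS1 = 12L, GS2 = 13L, PEPC = 10L, `PEPC-btpc` = 20L)[[preset]]
}

#' Write a simulated family to disk
#'
#' Emits CDS and protein FASTA, GFF3 gene structures (each CDS split into
#' a preset number of exons separated by fixed-length introns), Newick
#' gene tree, the ground-truth event log (TSV) and the true cluster
#' assignment table.
#'
#' @param sim result of [simulate_gene_tree()].
#' @param alignment a [codon_aln] over the gene-tree leaves (gap-free).
#' @param out_dir output directory.
#' @param family family label used in file names and the cluster table.
#' @param structure_preset exon-count preset, see [exon_count_preset()].
#' @param intron_length intron length in bp used between exons.
#' @param overwrite set TRUE to allow overwriting existing files.
#' @return invisibly, named character vector of written paths.
#' @export
emit_family_bundle <- function(sim, alignment, out_dir, family = "fam",
                               structure_preset = "GS1",
                               intron_length = 100L, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(cds = file.path(out_dir, paste0(family, "_cds.fasta")),
             protein = file.path(out_dir, paste0(family, "_protein.fasta")),
             gff = file.path(out_dir, paste0(family, ".gff3")),
             tree = file.path(out_dir, paste0(family, ".nwk")),
             events = file.path(out_dir, paste0(family, "_events.tsv")),
             clusters = file.path(out_dir, paste0(family, "_clusters.tsv")))
  exists <- file.exists(paths)
  if (any(exists) && !overwrite)
    stop("refusing to overwrite: ", paste(paths[exists], collapse = ", "),
         " (set overwrite = TRUE)")

  if (sim$n_leaves == 0L || is.null(alignment) || nrow(alignment) == 0L) {
    warning("empty family: no FASTA records written")
    for (p in paths[c("cds", "protein")]) cat("", file = p)
  } else {
    seqs <- aln_to_strings(alignment)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                paths[["cds"]], width = 60L)
    prot <- translate_alignment_rows(alignment)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                                paths[["protein"]], width = 60L)
    n_exons <- exon_count_preset(structure_preset)
    gff <- c("##gff-version 3")
    for (i in seq_along(seqs)) {
      id <- names(seqs)[i]
      cds_len <- nchar(seqs[[i]])
      # split CDS into n_exons pieces, remainder on the last exon
      base <- cds_len %/% n_exons
      sizes <- rep(base, n_exons)
      sizes[n_exons] <- sizes[n_exons] + cds_len - sum(sizes)
      starts <- cumsum(c(1L, utils::head(sizes, -1) + intron_length))
      ends <- starts + sizes - 1L
      span <- c(1L, max(ends))
      phase <- (3L - (cumsum(c(0L, sizes)) %% 3L)) %% 3L
      phase <- phase[seq_len(n_exons)]
      gff <- c(gff,
        sprintf("%s\tgenefamevo\tgene\t%d\t%d\t.\t+\t.\tID=%s", id, span[1],
                span[2], id),
        sprintf("%s\tgenefamevo\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                id, span[1], span[2], id, id),
        sprintf("%s\tgenefamevo\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1",
                id, starts, ends, id),
        sprintf("%s\tgenefamevo\tCDS\t%d\t%d\t.\t+\t%d\tParent=%s.t1",
                id, starts, ends, phase, id))
    }
    writeLines(gff, paths[["gff"]])
  }
  if (!is.null(sim$tree)) ape::write.tree(sim$tree, paths[["tree"]]) else
    cat("", file = paths[["tree"]])
  utils::write.table(sim$events, paths[["events"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cluster_tab <- data.frame(gene = sim$leaf_map$leaf,
                            cluster = rep(family,
                                          length(sim$leaf_map$leaf)))
  utils::write.table(cluster_tab, paths[["clusters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
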