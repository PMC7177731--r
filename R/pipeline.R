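# Orchestration: simulate-or-load, cluster, QC, tree, reconcile,
# selection, report. Also ships the published summary tables for the
# narrow-leafed lupin GS/PEPC families as packaged fixtures and provides
# simple query helpers over them.

#' Load a packaged printed summary table
#'
#' Three reference tables for the narrow-leafed lupin GS/PEPC families
#' are shipped as plain CSV fixtures: `"regions"` (scaffold/BAC region
#' characteristics: GC percent, repeat content, CDS counts; 18 rows),
#' `"expression"` (normalized leaf expression of the gene variants plus
#' two reference genes; 20 rows) and `"primers"` (probe amplification
#' primers; 2 rows).
#'
#' @param name one of "regions", "expression", "primers".
#' @return data.frame.
#' @export
load_printed_table <- function(name = c("regions", "expression", "primers")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "genefamevo", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  expected <- c(regions = 18L, expression = 20L, primers = 2L)
  if (nrow(tab) != expected[[name]])
    stop("fixture ", name, " has ", nrow(tab), " rows, expected ",
         expected[[name]])
  tab
}

#' Query a printed table
#'
#' @param table data.frame (see [load_printed_table()]).
#' @param column numeric column to summarize.
#' @param stat one of "max", "min", "mean".
#' @param subset_rows optional logical or integer row subset.
#' @param id_column column naming rows (used to report which row attains
#'   an extreme); default first column.
#' @return list with `value` and, for extremes, `row_id`.
#' @export
table_summary <- function(table, column, stat = c("max", "min", "mean"),
                          subset_rows = NULL, id_column = NULL) {
  stat <- match.arg(stat)
  if (!column %in% names(table)) stop("no column ", column)
  if (is.null(id_column)) id_column <- names(table)[1]
  tab <- if (is.null(subset_rows)) table else
    table[subset_rows, , drop = FALSE]
  x <- tab[[column]]
  keep <- !is.na(x)
  x <- x[keep]
  if (length(x) == 0) stop("no non-missing values")
  if (stat == "mean") return(list(value = mean(x)))
  idx <- if (stat == "max") which.max(x) else which.min(x)
  list(value = x[idx], row_id = tab[[id_column]][keep][idx])
}

#' Keep clusters containing any seed sequence
#'
#' Implements supervised cluster retention: only clusters intersecting
#' the golden-standard seed set (e.g. curated GS/PEPC hits) are kept.
#'
#' @param clustering a `gene_clustering`.
#' @param seed_ids non-empty character vector of sequence ids.
#' @return `gene_clustering` restricted to the retained clusters.
#' @export
keep_clusters_containing <- function(clustering, seed_ids) {
  if (length(seed_ids) == 0) stop("seed_ids is empty")
  present <- intersect(seed_ids, names(clustering$labels))
  if (length(present) == 0) stop("no cluster contains any seed id")
  keep_clusters <- unique(clustering$labels[present])
  labels <- clustering$labels[clustering$labels %in% keep_clusters]
  out <- clustering
  out$labels <- labels
  out$n_clusters <- length(unique(labels))
  out
}

#' Configuration for a simulated family analysis run
#'
#' @param species_newick species tree Newick string (time units).
#' @param wgd_events optional WGD table (see [species_tree_spec()]).
#' @param birth,death,tandem_fraction birth-death parameters.
#' @param n_codons simulated alignment length.
#' @param kappa,props,omegas,foreground codon-model settings (see
#'   [codon_sim_params()]).
#' @param subs_per_time expected substitutions per codon site per time
#'   unit, used to rescale the gene tree for sequence simulation.
#' @param seed master seed; stage seeds are derived from it.
#' @param stages character vector of stages to run, from
#'   `c("simulate", "qc", "tree", "reconcile", "selection")`.
#' @param use_inferred_tree reconcile the NJ tree instead of the true
#'   simulated tree (requires rooting by the true root; default FALSE).
#' @return list of class `family_run_config`.
#' @export
family_run_config <- function(species_newick, wgd_events = NULL,
                              birth = 0.1, death = 0.05,
                              tandem_fraction = 0.1, n_codons = 300L,
                              kappa = 2, props = c(0.7, 0.3, 0),
                              omegas = c(0.1, 1, 1),
                              foreground = character(0),
                              subs_per_time = 0.2, seed = 1L,
                              stages = c("simulate", "qc", "tree",
                                         "reconcile", "selection"),
                              use_inferred_tree = FALSE) {
  structure(list(species_newick = species_newick, wgd_events = wgd_events,
                 birth = birth, death = death,
                 tandem_fraction = tandem_fraction, n_codons = n_codons,
                 kappa = kappa, props = props, omegas = omegas,
                 foreground = foreground, subs_per_time = subs_per_time,
                 seed = as.integer(seed), stages = stages,
                 use_inferred_tree = use_inferred_tree),
            class = "family_run_config")
}

# cherry (sister-leaf) pairs of a tree
cherry_pairs <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- list()
  for (v in unique(tree$edge[, 1])) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    tipch <- ch[ch <= n_tip]
    if (length(tipch) == 2L)
      out[[length(out) + 1L]] <- tree$tip.label[sort(tipch)]
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Run a full simulated family analysis
#'
#' Simulates a gene family and codon alignment along the configured
#' species tree, quality-controls the alignment, builds an NJ tree with
#' bootstrap support, reconciles the (true or inferred) gene tree with
#' the species tree, classifies duplication timing, and computes Ka/Ks
#' for sister-leaf pairs. Stages can be toggled; the report is a plain
#' list that serializes deterministically to JSON for a fixed seed.
#'
#' @param config a [family_run_config()].
#' @param out_dir optional directory: the report (JSON) and simulation
#'   bundle are written there.
#' @return report list with one named block per executed stage.
#' @export
run_family_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "family_run_config"))
  stages <- config$stages
  report <- list(seed = config$seed, stages = stages)
  species <- species_tree_spec(config$species_newick, config$wgd_events)

  if (!"simulate" %in% stages)
    stop("the simulated pipeline requires the 'simulate' stage")
  sim <- simulate_gene_tree(species, family_sim_params(
    birth = config$birth, death = config$death,
    tandem_fraction = config$tandem_fraction,
    seed = derive_seed(config$seed, "family")))
  report$simulate <- list(n_leaves = sim$n_leaves,
                          n_duplications = sum(sim$events$event %in%
                            c("duplication", "tandem_duplication",
                              "wgd_retention")),
                          n_losses = sum(sim$events$event == "loss"))
  if (sim$n_leaves < 3L) {
    report$note <- "family too small after simulation; downstream skipped"
    return(report)
  }
  gtree <- sim$tree
  gtree_subs <- gtree
  gtree_subs$edge.length <- gtree$edge.length * config$subs_per_time
  aln <- simulate_codon_alignment(gtree_subs, codon_sim_params(
    kappa = config$kappa, props = config$props, omegas = config$omegas,
    foreground = config$foreground, n_codons = config$n_codons,
    seed = derive_seed(config$seed, "alignment")))

  if ("qc" %in% stages) {
    D <- gap_distance_matrix(aln)
    outliers <- if (nrow(aln) >= 4L) detect_outliers(D) else character(0)
    aln_qc <- trim_by_occupancy(aln, 0.7)
    report$qc <- list(n_outliers = length(outliers),
                      outliers = as.list(outliers),
                      columns_kept = ncol(aln_qc))
  } else aln_qc <- aln

  if ("tree" %in% stages) {
    nj <- bootstrap_support(aln_qc, n_replicates = 100L,
                            seed = derive_seed(config$seed, "bootstrap"))
    report$tree <- list(
      n_tips = length(nj$tip.label),
      mean_support = mean(as.numeric(nj$node.label), na.rm = TRUE))
  }

  rec <- NULL
  if ("reconcile" %in% stages) {
    rec_tree <- if (config$use_inferred_tree && "tree" %in% stages) {
      stop("inferred-tree reconciliation requires an outgroup; ",
           "use the true tree for simulated runs")
    } else gtree
    rec <- lca_reconcile(rec_tree, species$tree, sim$leaf_map)
    timing <- classify_duplication_timing(rec)
    report$reconcile <- list(D = rec$D, L = rec$L, cost = rec$cost,
                             timing = timing)
  }

  if ("selection" %in% stages) {
    pairs <- cherry_pairs(gtree)
    if (!is.null(pairs)) {
      kk <- kaks_pair_table(aln, pairs)
      report$selection <- list(n_pairs = nrow(kk), kaks = kk)
    } else {
      report$selection <- list(n_pairs = 0L)
    }
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    emit_family_bundle(sim, aln, out_dir, family = "family",
                       overwrite = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}
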