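# Gene-family, codon-alignment and droplet simulators.

sp3 <- species_tree_spec("((A:1,B:1)N2:1,C:2)root;")

test_that("zero-rate simulation reproduces the species tree exactly", {
  sim <- simulate_gene_tree(sp3, family_sim_params(seed = 5))
  expect_equal(sim$n_leaves, 3L)
  expect_equal(sort(sim$leaf_map$species), c("A", "B", "C"))
  expect_true(all(sim$events$event == "speciation"))
  # topology congruent with the species tree
  g <- sim$tree
  g$tip.label <- sim$leaf_map$species[match(g$tip.label, sim$leaf_map$leaf)]
  expect_equal(ape::dist.topo(ape::unroot(g), ape::unroot(sp3$tree)), 0,
               ignore_attr = TRUE)
})

test_that("deterministic WGD retention doubles or triples every species", {
  for (mult in 2:3) {
    sp <- species_tree_spec("(A:1,B:1)root;", wgd_events = data.frame(
      branch = "root", time_frac = 0.5, retention = 1, multiplicity = mult))
    sim <- simulate_gene_tree(sp, family_sim_params(seed = 3))
    expect_true(all(table(sim$leaf_map$species) == mult))
    expect_equal(sum(sim$events$event == "wgd_retention"), mult - 1L)
    check_event_conservation(sim, sp)
  }
})

test_that("parameter validation rejects bad rates and WGD settings", {
  expect_error(family_sim_params(birth = -1), "rates")
  expect_error(family_sim_params(tandem_fraction = 2), "tandem_fraction")
  expect_error(species_tree_spec("(A:1,B:1);", wgd_events = data.frame(
    branch = "root", time_frac = 0.5, retention = 1, multiplicity = 4)),
    "multiplicity")
  expect_error(species_tree_spec("(A:1,B:1);", wgd_events = data.frame(
    branch = "Z", time_frac = 0.5, retention = 1, multiplicity = 2)),
    "not in tree")
})

test_that("lineage bookkeeping holds across random simulations", {
  for (seed in 1:25) {
    sim <- simulate_gene_tree(sp3, family_sim_params(
      birth = 0.4, death = 0.3, tandem_fraction = 0.3, seed = seed))
    expect_true(check_event_conservation(sim, sp3))
  }
})

test_that("single-branch survival matches the birth-death expectation", {
  # E[copies at t] = exp((birth - death) t) for one starting lineage
  sp1 <- species_tree_spec("(A:1);")
  birth <- 0.6; death <- 0.2; t <- 1
  n_rep <- 2000L
  copies <- vapply(seq_len(n_rep), function(s)
    simulate_gene_tree(sp1, family_sim_params(birth, death,
                                              seed = s))$n_leaves,
    integer(1))
  expected <- exp((birth - death) * t)
  se <- sd(copies) / sqrt(n_rep)
  expect_lt(abs(mean(copies) - expected), 3 * se)
})

test_that("codon simulation respects branch lengths and kappa", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln0 <- simulate_codon_alignment(tr, codon_sim_params(n_codons = 50,
                                                        seed = 2))
  expect_identical(unclass(aln0)["A", ], unclass(aln0)["B", ])

  tr2 <- ape::read.tree(text = "(A:0.3,B:0.3);")
  ts_frac <- function(kappa, seed) {
    aln <- simulate_codon_alignment(tr2, codon_sim_params(
      kappa = kappa, props = c(0, 1, 0), omegas = c(0.5, 1, 1),
      n_codons = 400, seed = seed))
    a <- strsplit(aln_to_strings(aln)[1], "")[[1]]
    b <- strsplit(aln_to_strings(aln)[2], "")[[1]]
    d <- which(a != b)
    pur <- c(A = "R", G = "R", C = "Y", T = "Y")
    mean(pur[a[d]] == pur[b[d]])
  }
  wins <- vapply(1:50, function(s) ts_frac(8, s) > ts_frac(1, s + 1000),
                 logical(1))
  expect_gt(mean(wins), 0.9)     # transitions dominate at high kappa
})

test_that("simulated codon frequencies approach the target distribution", {
  # long single branch, equal frequencies
  tr <- ape::read.tree(text = "(A:25,B:25);")
  aln <- simulate_codon_alignment(tr, codon_sim_params(
    props = c(0, 1, 0), omegas = c(0.5, 1, 1), n_codons = 5000, seed = 4))
  obs <- table(factor(unclass(aln), levels = sense_codons()))
  gof <- suppressWarnings(chisq.test(obs, p = rep(1 / 61, 61)))
  expect_gt(gof$p.value, 0.01)
})

test_that("alignment simulation rejects invalid trees", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  tr$edge.length[1] <- -0.1
  expect_error(simulate_codon_alignment(tr, codon_sim_params(n_codons = 10)),
               "negative")
})

test_that("droplet simulation matches the Poisson zero class", {
  a0 <- simulate_droplets(1000, 0, seed = 1)
  expect_equal(a0$n_negative, a0$n_total)
  expect_error(simulate_droplets(1000, -1), "lambda")

  a <- simulate_droplets(17000, log(2), seed = 7)
  p_hat <- a$n_negative / a$n_total
  se <- sqrt(0.5 * 0.5 / 17000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("family bundles round-trip and follow structure presets", {
  sim <- simulate_gene_tree(sp3, family_sim_params(seed = 5))
  aln <- simulate_codon_alignment(sim$tree, codon_sim_params(
    n_codons = 60, seed = 6))
  out <- file.path(tempfile(), "bundle")
  paths <- emit_family_bundle(sim, aln, out, family = "gs1",
                              structure_preset = "GS1")
  back <- read_codon_alignment(paths[["cds"]])
  expect_identical(aln_to_strings(back), aln_to_strings(aln))
  re_tree <- ape::read.tree(paths[["tree"]])
  expect_equal(ape::dist.topo(ape::unroot(re_tree), ape::unroot(sim$tree)),
               0, ignore_attr = TRUE)

  gff <- readLines(paths[["gff"]])
  exons <- grep("\texon\t", gff, value = TRUE)
  expect_equal(length(exons), 12L * sim$n_leaves)   # GS1 preset: 12 exons

  expect_error(emit_family_bundle(sim, aln, out, family = "gs1"),
               "refusing to overwrite")

  empty <- list(n_leaves = 0L, tree = NULL,
                leaf_map = data.frame(leaf = character(0),
                                      species = character(0)),
                events = data.frame(event = character(0),
                                    node_id = character(0),
                                    species_branch = character(0),
                                    time = numeric(0)))
  expect_warning(emit_family_bundle(empty, NULL, out, family = "none"),
                 "empty family")
})
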