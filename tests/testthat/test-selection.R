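# NG86 Ka/Ks and the branch-site likelihood machinery.

test_that("NG86 handles hand-counted and degenerate cases", {
  r0 <- ng86_kaks("ATGAAA", "ATGAAA")
  expect_equal(c(r0$Ka, r0$Ks), c(0, 0))
  expect_true(is.na(r0$ratio))

  # GGT: fourfold-degenerate third position; one synonymous difference
  r <- ng86_kaks("GGTGGT", "GGCGGT")
  expect_equal(r$S, 2)
  expect_equal(r$N + r$S, 3 * r$n_codons)
  expect_equal(c(r$Sd, r$Nd), c(1, 0))
  expect_equal(r$pS, 0.5)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 4 * 0.5 / 3), tolerance = 1e-10)

  expect_error(ng86_kaks("ATGAAA", "ATG"), "length")
  expect_error(ng86_kaks("ATGTAA", "ATGAAA"), "stop")

  # gap codons are removed pairwise
  rg <- ng86_kaks(c("ATG", "---", "GGT"), c("ATG", "AAA", "GGC"))
  expect_equal(rg$n_codons, 2L)
})

test_that("NG86 counts agree with the path-enumeration oracle and are symmetric", {
  set.seed(31)
  for (k in 1:50) {
    s1 <- random_cds(25)
    s2 <- random_cds(25)
    got <- ng86_kaks(s1, s2)
    ref <- oracle_ng86(s1, s2)
    expect_equal(got$N, ref$N, tolerance = 1e-9)
    expect_equal(got$S, ref$S, tolerance = 1e-9)
    expect_equal(got$Nd, ref$Nd, tolerance = 1e-9)
    expect_equal(got$Sd, ref$Sd, tolerance = 1e-9)
    rev <- ng86_kaks(s2, s1)
    expect_equal(got$Ka, rev$Ka)
    expect_equal(got$Ks, rev$Ks)
  }
})

test_that("pair tables classify selection regimes from simulated data", {
  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")
  # strong purifying selection
  ratios_pur <- vapply(1:20, function(s) {
    aln <- simulate_codon_alignment(tr, codon_sim_params(
      props = c(1, 0, 0), omegas = c(0.1, 1, 1), n_codons = 800,
      seed = 400 + s))
    kaks_pair_table(aln, rbind(c("A", "B")))$ratio
  }, numeric(1))
  expect_gte(mean(ratios_pur < 0.5), 0.95)

  # neutral
  cls_neu <- vapply(1:20, function(s) {
    aln <- simulate_codon_alignment(tr, codon_sim_params(
      kappa = 1, props = c(0, 1, 0), omegas = c(0.5, 1, 1),
      n_codons = 1500, seed = 600 + s))
    kaks_pair_table(aln, rbind(c("A", "B")))$class
  }, character(1))
  expect_gte(mean(cls_neu == "neutral"), 0.85)

  aln <- simulate_codon_alignment(tr, codon_sim_params(n_codons = 50,
                                                       seed = 3))
  self <- kaks_pair_table(aln, rbind(c("A", "A")))
  expect_true(is.na(self$ratio))
  expect_error(kaks_pair_table(aln, rbind(c("A", "zz"))), "not in alignment")
})

test_that("codon log-likelihood matches exhaustive enumeration", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.25):0.15,C:0.3);")
  aln <- simulate_codon_alignment(tr, codon_sim_params(
    kappa = 3, props = c(0.5, 0.3, 0.2), omegas = c(0.3, 1, 4),
    foreground = "A", n_codons = 20, seed = 9))
  m <- branch_site_model(kappa = 3, omega0 = 0.3, omega2 = 4,
                         p0 = 0.5, p1 = 0.3, foreground = "A")
  ll <- codon_loglikelihood(tr, aln, m)

  # brute force over all internal-state pairs with a series expm
  codons <- sense_codons()
  pi <- equal_codon_freqs()
  sc <- codon_mixture_scale(3, pi, m$bg_omegas, m$props)
  st <- rbind(match(unclass(aln)["A", ], codons),
              match(unclass(aln)["B", ], codons),
              match(unclass(aln)["C", ], codons))
  cls_lik <- matrix(0, 4, 20)
  for (cl in 1:4) {
    Pm <- function(w, t)
      as.matrix(Matrix::expm(Matrix::Matrix(gy94_rate_matrix(3, w, pi) /
                                              sc * t)))
    PA <- Pm(m$fg_omegas[cl], 0.1); PB <- Pm(m$bg_omegas[cl], 0.25)
    PN <- Pm(m$bg_omegas[cl], 0.15); PC <- Pm(m$bg_omegas[cl], 0.3)
    for (s in 1:20) {
      tot <- 0
      for (r in 1:61) for (n in 1:61)
        tot <- tot + pi[r] * PN[r, n] * PA[n, st[1, s]] *
          PB[n, st[2, s]] * PC[r, st[3, s]]
      cls_lik[cl, s] <- tot
    }
  }
  ll_bf <- sum(log(colSums(m$props * cls_lik)))
  expect_equal(ll, ll_bf, tolerance = 1e-8)

  # single-sequence likelihood is the log product of frequencies
  a1 <- aln[1, ]
  expect_equal(codon_loglikelihood("A", a1, m), 20 * log(1 / 61),
               tolerance = 1e-12)

  # re-rooting invariance for a reversible model (foreground unchanged)
  tr2 <- ape::root(ape::unroot(tr), outgroup = "B", resolve.root = TRUE)
  expect_equal(codon_loglikelihood(tr2, aln, m), ll, tolerance = 1e-6)
})

test_that("branch-site model parameterization enforces model-A constraints", {
  m <- branch_site_model(kappa = 2, omega0 = 0.2, omega2 = 5,
                         p0 = 0.6, p1 = 0.2)
  expect_equal(sum(m$props), 1)
  expect_equal(m$props[3] / m$props[4], m$p0 / m$p1)
  expect_error(branch_site_model(2, omega0 = 1.5, p0 = .5, p1 = .5),
               "omega0")
  expect_error(branch_site_model(2, omega0 = .5, omega2 = .5,
                                 p0 = .5, p1 = .5), "omega2")
})

test_that("the LRT degenerates correctly and respects nesting", {
  # identical sequences: null and alternative coincide
  m <- matrix(rep(sample(sense_codons(), 60, TRUE), each = 4), 4, 60,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  aln <- codon_aln(m)
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  out <- branch_site_test(tr, aln, foreground = "a", codon_freqs = "equal")
  expect_equal(out$statistic, 0, tolerance = 1e-4)
  expect_gte(out$p_value, 0.99)
  expect_equal(nrow(out$neb_sites), 0L)
  expect_gte(out$lnL_alt, out$lnL_null)

  expect_error(branch_site_test(tr, aln, foreground = "zz"),
               "foreground branch not found")
})

test_that("a global branch-length scale can absorb a misscaled input tree", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  aln <- simulate_codon_alignment(tr, codon_sim_params(
    props = c(0.6, 0.4, 0), omegas = c(0.2, 1, 1), n_codons = 200,
    seed = 8))
  tr3 <- tr
  tr3$edge.length <- tr3$edge.length * 3
  fit_scaled <- branch_site_test(tr3, aln, foreground = "a",
                                 codon_freqs = "equal",
                                 estimate_scale = TRUE)
  fit_true <- branch_site_test(tr, aln, foreground = "a",
                               codon_freqs = "equal")
  # optimizing the scale recovers (at least) the true-scale fit
  expect_gte(fit_scaled$lnL_null, fit_true$lnL_null - 1)
})

test_that("chi-square p-values match the closed form for one df", {
  # for df = 1: P(X > x) = 2 * (1 - Phi(sqrt(x)))
  for (x in c(0.01, 0.5, 2.71, 3.84, 10, 25)) {
    expect_lt(abs(pchisq(x, 1, lower.tail = FALSE) -
                    2 * (1 - pnorm(sqrt(x)))), 1e-10)
  }
})

test_that("foreground tags in Newick are parsed and stripped", {
  got <- parse_foreground_newick("((a:1,b:1)n1#1:1,c:2);")
  expect_equal(got$foreground, "n1")
  expect_false(any(grepl("#", c(got$tree$tip.label, got$tree$node.label))))
  got2 <- parse_foreground_newick("((a#1:1,b:1):1,c:2);")
  expect_equal(got2$foreground, "a")
})
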