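# Region statistics, gene structures, microsynteny chaining, in-silico PCR.

test_that("region stats compute GC and merged repeat fractions", {
  r <- region_annotation("r1", sequence = "ATGC")
  expect_equal(region_stats(r)$gc_percent, 50)

  seq1k <- strrep("A", 1000)
  r2 <- region_annotation("r2", sequence = seq1k,
                          mask = data.frame(start = 100, end = 150,
                                            class = "Ty1/Copia"))
  s2 <- region_stats(r2)
  expect_equal(s2$repeat_percent, 5)
  expect_equal(s2$repeat_bp, 50)

  # ambiguity codes excluded from both numerator and denominator
  r3 <- region_annotation("r3", sequence = "ATGCNNNN")
  expect_equal(region_stats(r3)$gc_percent, 50)

  # overlapping intervals vs per-base brute force
  set.seed(5)
  iv <- data.frame(start = sample(0:900, 40, TRUE))
  iv$end <- iv$start + sample(10:120, 40, TRUE)
  iv$end <- pmin(iv$end, 1000)
  r4 <- region_annotation("r4", sequence = seq1k, mask = iv)
  covered <- rep(FALSE, 1000)
  for (k in seq_len(nrow(iv))) covered[(iv$start[k] + 1):iv$end[k]] <- TRUE
  expect_equal(region_stats(r4)$repeat_bp, sum(covered))
  # order invariance
  r5 <- region_annotation("r4", sequence = seq1k,
                          mask = iv[sample(nrow(iv)), ])
  expect_equal(region_stats(r5)$repeat_bp, sum(covered))

  expect_error(region_stats(region_annotation("x", sequence = "")), "")
})

test_that("family region summaries report means and extremes", {
  mk <- function(id, gc, rep_frac) {
    n <- 1000
    n_gc <- round(n * gc / 100)
    seqs <- paste0(strrep("G", n_gc), strrep("A", n - n_gc))
    region_stats(region_annotation(id, sequence = seqs,
      mask = if (rep_frac > 0)
        data.frame(start = 0, end = rep_frac * 10) else NULL))
  }
  stats <- list(mk("x1", 33.1, 8.58), mk("x2", 32.9, 15.63),
                mk("x3", 33.0, 0))
  s <- summarize_family_regions(stats, "GS")
  expect_equal(s$mean_gc, 33)
  expect_equal(s$max_repeat_region, "x2")
  expect_equal(s$min_repeat_percent, 0)
  single <- summarize_family_regions(stats[1], "GS")
  expect_equal(single$mean_gc, round(stats[[1]]$gc_percent, 2))
})

test_that("gene structure summaries convert CDS to protein lengths", {
  genes <- data.frame(gene = c("GS2a1", "PEPC5", "g3", "g4"),
                      exon_count = c(12, 20, 12, 13),
                      cds_length_bp = c(1299, 3135, 1299, 1302))
  out <- gene_structure_summary(genes)
  expect_equal(out$table$protein_length_aa[1], 432)   # 1299 bp
  expect_equal(out$table$protein_length_aa[2], 1044)  # 3135 bp
  expect_equal(out$exon_mode, 12L)
  expect_true(all(3 * (out$table$protein_length_aa + 1) ==
                    out$table$cds_length_bp))

  ties <- gene_structure_summary(data.frame(
    gene = c("a", "b"), exon_count = c(12, 13),
    cds_length_bp = c(300, 300)))
  expect_setequal(ties$exon_mode, c(12L, 13L))

  expect_error(gene_structure_summary(data.frame(
    gene = "bad", exon_count = 3, cds_length_bp = 100)), "divisible by 3")
})

test_that("anchor chaining finds forward and inversion blocks", {
  fwd <- data.frame(a_idx = 1:3, b_idx = 1:3)
  blocks <- microsynteny_chain(fwd)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$orientation, "forward")
  expect_equal(blocks[[1]]$length, 3L)

  inv <- data.frame(a_idx = 1:3, b_idx = 3:1)
  bi <- microsynteny_chain(inv)
  expect_equal(bi[[1]]$orientation, "inversion")
  expect_equal(bi[[1]]$length, 3L)

  # monotonicity within every reported block
  set.seed(77)
  noise <- data.frame(a_idx = sample(100, 40), b_idx = sample(100, 40))
  planted <- data.frame(a_idx = 50:55, b_idx = 60:65)
  anc <- unique(rbind(noise, planted))
  blocks2 <- microsynteny_chain(anc, max_gap = 5, min_block = 3)
  for (b in blocks2) {
    expect_true(all(diff(b$anchors$a_idx) > 0))
    db <- diff(b$anchors$b_idx)
    expect_true(all(db > 0) || all(db < 0))
  }
  # the planted diagonal is recovered as one block
  hit <- vapply(blocks2, function(b)
    all(paste(planted$a_idx, planted$b_idx) %in%
          paste(b$anchors$a_idx, b$anchors$b_idx)), logical(1))
  expect_true(any(hit))

  expect_error(microsynteny_chain(rbind(fwd, fwd)), "deduplicated")
})

test_that("planted diagonals are recovered across random noise fields", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    noise <- unique(data.frame(a_idx = sample(100, 40, TRUE),
                               b_idx = sample(100, 40, TRUE)))
    a0 <- sample(20:70, 1)
    planted <- data.frame(a_idx = a0:(a0 + 5), b_idx = (a0 + 3):(a0 + 8))
    anc <- unique(rbind(noise, planted))
    blocks <- microsynteny_chain(anc, max_gap = 5, min_block = 3)
    ok <- any(vapply(blocks, function(b)
      all(paste(planted$a_idx, planted$b_idx) %in%
            paste(b$anchors$a_idx, b$anchors$b_idx)), logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 28L)
})

test_that("BED and GFF3 readers round-trip emitted annotations", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\tTy1/Copia", "chr1\t400\t420\tGypsy"), bed)
  iv <- read_masked_bed(bed)
  expect_equal(iv$start, c(100, 400))
  expect_equal(iv$end, c(150, 420))
  expect_equal(iv$class, c("Ty1/Copia", "Gypsy"))

  sp <- species_tree_spec("((A:1,B:1)N2:1,C:2)root;")
  sim <- simulate_gene_tree(sp, family_sim_params(seed = 5))
  aln <- simulate_codon_alignment(sim$tree, codon_sim_params(
    n_codons = 60, seed = 6))
  out <- file.path(tempfile(), "b")
  paths <- emit_family_bundle(sim, aln, out, family = "fam",
                              structure_preset = "GS2")
  genes <- read_gene_structures(paths[["gff"]])
  expect_equal(nrow(genes), 3L)
  expect_true(all(genes$exon_count == 13L))   # GS2 preset
  expect_true(all(genes$cds_length_bp == 180))
  gs <- gene_structure_summary(genes)
  expect_equal(gs$exon_mode, 13L)
})

test_that("in-silico PCR finds constructed products", {
  set.seed(3)
  fwdp <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  revp <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  template <- paste0(fwdp, mid, revcomp(revp))
  prod <- insilico_pcr(template, fwdp, revp)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$product_length, 140L)

  expect_equal(nrow(insilico_pcr(template, fwdp, fwdp)), 0L)

  # two forward sites give two products sorted by start
  template2 <- paste0(fwdp, mid, fwdp, mid, revcomp(revp))
  prod2 <- insilico_pcr(template2, fwdp, revp)
  expect_equal(nrow(prod2), 2L)
  expect_true(all(diff(prod2$start) > 0))
  expect_error(insilico_pcr(template, "ACGT", revp), "15 nt")
})
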