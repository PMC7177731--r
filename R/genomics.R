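# Genome-region characterization (GC content, repeat fraction, gene
# structures) and microsynteny detection by chaining homology anchors.
# Repeat detection and gene prediction are upstream tools whose outputs
# are consumed here as masked intervals and gene feature tables.

#' Region annotation container
#'
#' @param id region identifier.
#' @param sequence nucleotide string (may be NULL if only `length` known).
#' @param length region length in bp (derived from `sequence` if absent).
#' @param mask data.frame of masked repeat intervals with columns
#'   `start`, `end` (0-based half-open) and optional `class`.
#' @param genes data.frame of gene features with columns `gene`,
#'   `exon_count`, `cds_length_bp` (see [gene_structure_summary()]).
#' @return object of class `region_annotation`.
#' @export
region_annotation <- function(id, sequence = NULL, length = NULL,
                              mask = NULL, genes = NULL) {
  if (is.null(length)) {
    if (is.null(sequence)) stop("need sequence or length")
    length <- nchar(sequence)
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    if (any(mask$start < 0 | mask$end > length | mask$start >= mask$end))
      stop("mask intervals must satisfy 0 <= start < end <= length")
  }
  structure(list(id = id, sequence = sequence, length = length,
                 mask = mask, genes = genes),
            class = "region_annotation")
}

#' Read masked repeat intervals from a BED file
#'
#' BED intervals are 0-based half-open, the convention used by repeat
#' maskers; the optional name column is kept as the repeat class.
#'
#' @param path BED file path.
#' @return data.frame with columns start, end and (when present) class,
#'   suitable for [region_annotation()].
#' @export
read_masked_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_masked_bed() needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$class <- nm
  out
}

#' Read gene structures from a GFF3 file
#'
#' Collapses exon and CDS features per gene into the flat table consumed
#' by [gene_structure_summary()] and [region_annotation()].
#'
#' @param path GFF3 file path.
#' @return data.frame with columns gene, exon_count, cds_length_bp.
#' @export
read_gene_structures <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_structures() needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "GFF3")
  seqid <- as.character(GenomeInfoDb::seqnames(gr))
  type <- as.character(gr$type)
  w <- BiocGenerics::width(gr)
  genes <- unique(seqid[type == "gene"])
  if (length(genes) == 0) genes <- unique(seqid)
  data.frame(
    gene = genes,
    exon_count = vapply(genes, function(g)
      sum(type == "exon" & seqid == g), integer(1)),
    cds_length_bp = vapply(genes, function(g)
      sum(w[type == "CDS" & seqid == g]), numeric(1)),
    row.names = NULL)
}

#' GC, repeat and gene-content statistics of a region
#'
#' GC percent is (G+C)/(A+C+G+T) x 100 with ambiguity codes excluded
#' from both numerator and denominator; the repeat fraction uses the
#' merged masked intervals; `cds_count` is the number of gene features
#' carrying a CDS.
#'
#' @param region a [region_annotation()] with a sequence.
#' @return list: id, gc_percent, repeat_percent, repeat_bp,
#'   repeat_classes, cds_count, length.
#' @export
region_stats <- function(region) {
  stopifnot(inherits(region, "region_annotation"))
  if (is.null(region$sequence) || nchar(region$sequence) == 0)
    stop("region has no sequence")
  counts <- table(strsplit(toupper(region$sequence), "")[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  if (acgt == 0) stop("sequence has no unambiguous bases")
  repeat_bp <- 0L
  repeat_classes <- character(0)
  if (!is.null(region$mask) && nrow(region$mask) > 0) {
    ir <- IRanges::reduce(IRanges::IRanges(start = region$mask$start + 1L,
                                           end = region$mask$end))
    repeat_bp <- sum(IRanges::width(ir))
    if (!is.null(region$mask$class))
      repeat_classes <- sort(unique(region$mask$class))
  }
  cds_count <- if (is.null(region$genes)) 0L else
    sum(region$genes$cds_length_bp > 0, na.rm = TRUE)
  list(id = region$id,
       gc_percent = 100 * gc / acgt,
       repeat_percent = 100 * repeat_bp / region$length,
       repeat_bp = repeat_bp,
       repeat_classes = repeat_classes,
       cds_count = cds_count,
       length = region$length)
}

#' Summarize region statistics over a gene family
#'
#' @param stats list of [region_stats()] outputs.
#' @param family family label.
#' @return list: family, n_regions, mean_gc (2 decimals), min/max repeat
#'   percent with the region ids attaining them, mean_cds_count.
#' @export
summarize_family_regions <- function(stats, family = "") {
  if (length(stats) == 0) stop("no regions")
  gc <- vapply(stats, function(s) s$gc_percent, numeric(1))
  rp <- vapply(stats, function(s) s$repeat_percent, numeric(1))
  ids <- vapply(stats, function(s) s$id, character(1))
  cds <- vapply(stats, function(s) as.numeric(s$cds_count), numeric(1))
  list(family = family, n_regions = length(stats),
       mean_gc = round(mean(gc), 2),
       min_repeat_percent = min(rp), min_repeat_region = ids[which.min(rp)],
       max_repeat_percent = max(rp), max_repeat_region = ids[which.max(rp)],
       mean_cds_count = round(mean(cds), 2))
}

#' Gene structure summary (exon counts, CDS and protein lengths)
#'
#' For complete genes (start codon through stop) the protein length is
#' `cds_length/3 - 1` residues: the stop codon is counted in the CDS but
#' not in the protein. The modal exon count of the family is reported,
#' with ties returned as a vector.
#'
#' @param genes data.frame with columns `gene`, `exon_count`,
#'   `cds_length_bp` and optional logical `complete` (default TRUE).
#' @return list with `table` (adds `protein_length_aa`) and `exon_mode`.
#' @export
gene_structure_summary <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "exon_count", "cds_length_bp") %in% names(genes)))
  complete <- if ("complete" %in% names(genes)) genes$complete else
    rep(TRUE, nrow(genes))
  bad <- complete & (genes$cds_length_bp %% 3L != 0L)
  if (any(bad))
    stop("complete CDS length not divisible by 3 for: ",
         paste(genes$gene[bad], collapse = ", "))
  prot <- ifelse(complete, genes$cds_length_bp / 3 - 1, NA_real_)
  tab <- cbind(genes, protein_length_aa = prot)
  counts <- table(genes$exon_count)
  mode <- as.integer(names(counts)[counts == max(counts)])
  list(table = tab, exon_mode = mode)
}

#' Detect collinear microsynteny blocks by chaining anchors
#'
#' Finds maximal chains of homology anchors monotonically increasing in
#' both regions (forward blocks) or increasing in A while decreasing in
#' B (inversion blocks), with ordinal index gaps of at most `max_gap`
#' between consecutive anchors. Chains are scored by summed anchor score
#' and extracted by weighted longest-increasing-subsequence dynamic
#' programming (best chain first, anchors removed, repeated); chains
#' shorter than `min_block` anchors are discarded.
#'
#' @param anchors data.frame with columns `a_idx`, `b_idx` (ordinal gene
#'   positions, deduplicated) and optional `score` (default 1).
#' @param max_gap maximum skipped indices between consecutive anchors.
#' @param min_block minimum anchors per reported block.
#' @return list of blocks: each a list with `anchors` (data.frame),
#'   `orientation` ("forward"/"inversion"), `score`, `length`.
#' @export
microsynteny_chain <- function(anchors, max_gap = 5L, min_block = 3L) {
  stopifnot(is.data.frame(anchors),
            all(c("a_idx", "b_idx") %in% names(anchors)))
  if (anyDuplicated(anchors[, c("a_idx", "b_idx")]))
    stop("anchors must be deduplicated")
  if (is.null(anchors$score)) anchors$score <- 1
  avail <- anchors

  best_chain <- function(df, orientation) {
    if (nrow(df) == 0) return(NULL)
    b <- if (orientation == "forward") df$b_idx else -df$b_idx
    ord <- order(df$a_idx, b)
    df <- df[ord, , drop = FALSE]
    b <- b[ord]
    n <- nrow(df)
    dp <- df$score
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok <- df$a_idx[i] > df$a_idx[j] && b[i] > b[j] &&
          df$a_idx[i] - df$a_idx[j] - 1L <= max_gap &&
          abs(df$b_idx[i] - df$b_idx[j]) - 1L <= max_gap
        if (ok && dp[j] + df$score[i] > dp[i]) {
          dp[i] <- dp[j] + df$score[i]
          prev[i] <- j
        }
      }
    }
    end <- which.max(dp)
    chain <- integer(0)
    v <- end
    while (!is.na(v)) { chain <- c(v, chain); v <- prev[v] }
    list(anchors = df[chain, c("a_idx", "b_idx", "score"), drop = FALSE],
         orientation = orientation, score = dp[end], length = length(chain))
  }

  blocks <- list()
  repeat {
    fwd <- best_chain(avail, "forward")
    inv <- best_chain(avail, "inversion")
    cand <- Filter(function(x) !is.null(x) && x$length >= min_block,
                   list(fwd, inv))
    if (length(cand) == 0) break
    scores <- vapply(cand, function(x) x$score, numeric(1))
    blk <- cand[[which.max(scores)]]
    rownames(blk$anchors) <- NULL
    blocks[[length(blocks) + 1L]] <- blk
    key <- paste(avail$a_idx, avail$b_idx)
    used <- paste(blk$anchors$a_idx, blk$anchors$b_idx)
    avail <- avail[!(key %in% used), , drop = FALSE]
  }
  blocks
}

#' In-silico PCR
#'
#' Finds forward-primer matches on the plus strand and downstream
#' reverse-complemented reverse-primer matches within `max_product` bp.
#' Product length includes both primers.
#'
#' @param template nucleotide string.
#' @param fwd,rev primer sequences (>= 15 nt).
#' @param max_mismatch allowed mismatches per primer (default 0).
#' @param max_product maximum product length in bp (default 5000).
#' @return data.frame: start, end, product_length (1-based, sorted by
#'   start); zero rows when no product.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                         max_product = 5000L) {
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt")
  subject <- Biostrings::DNAString(toupper(template))
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(fwd)),
                                    subject, max.mismatch = max_mismatch)
  rpat <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev)))
  rhits <- Biostrings::matchPattern(rpat, subject,
                                    max.mismatch = max_mismatch)
  out <- data.frame(start = integer(0), end = integer(0),
                    product_length = integer(0))
  for (i in seq_along(fhits)) {
    fs <- Biostrings::start(fhits)[i]
    for (j in seq_along(rhits)) {
      re <- Biostrings::end(rhits)[j]
      if (re > Biostrings::end(fhits)[i] && re - fs + 1L <= max_product)
        out <- rbind(out, data.frame(start = fs, end = re,
                                     product_length = re - fs + 1L))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}
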