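# Codon-alignment quality control: gap-pattern outlier rejection,
# occupancy-based column trimming, protein-to-codon back-translation and
# rare-codon-column masking for selection analyses. All column operations
# act on whole codon columns so the reading frame is never broken.

#' Pairwise gap-pattern distance matrix
#'
#' Hamming distance between the binary gap masks (per codon column) of
#' every pair of rows. Sequences with similar gap architecture are close;
#' truncated or mispredicted genes stand out.
#'
#' @param aln a [codon_aln] with at least 2 sequences.
#' @return symmetric integer matrix with zero diagonal.
#' @export
gap_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_aln"))
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  g <- gap_mask(aln) * 1L
  # Hamming distance via cross products of the mask and its complement
  same11 <- tcrossprod(g)
  same00 <- tcrossprod(1L - g)
  D <- ncol(aln) - same11 - same00
  dimnames(D) <- list(rownames(aln), rownames(aln))
  diag(D) <- 0L
  D
}

#' Flag gap-pattern outlier sequences
#'
#' A sequence is flagged when its mean gap distance to all other
#' sequences exceeds the mean plus `z_threshold` standard deviations of
#' the per-sequence mean distances, the reference statistics being
#' computed with the candidate itself excluded. Applied in a single pass.
#'
#' @param D matrix from [gap_distance_matrix()].
#' @param z_threshold number of standard deviations (default 2.5).
#' @return character vector of flagged sequence ids (possibly empty).
#' @export
detect_outliers <- function(D, z_threshold = 2.5) {
  n <- nrow(D)
  if (n < 4L) {
    warning("fewer than 4 sequences: outlier detection skipped")
    return(character(0))
  }
  mean_d <- rowSums(D) / (n - 1L)
  flagged <- vapply(seq_len(n), function(i) {
    ref <- mean_d[-i]
    s <- stats::sd(ref)
    if (!is.finite(s) || s == 0) return(mean_d[i] > mean(ref))
    mean_d[i] > mean(ref) + z_threshold * s
  }, logical(1))
  rownames(D)[flagged]
}

#' Trim codon columns by occupancy
#'
#' Removes codon columns whose non-gap fraction (over all rows) is below
#' `min_occupancy`. Columns are removed as whole codons, so framing is
#' preserved. The 70% threshold is the species-tree filtering preset; a
#' permissive preset retaining all columns with more than 1% occupancy
#' (`min_occupancy = 0.01`) is used ahead of outlier screening.
#'
#' @param aln a [codon_aln].
#' @param min_occupancy required non-gap fraction in (0, 1].
#' @return trimmed `codon_aln`; attribute `removed_columns` lists the
#'   dropped codon column indices.
#' @export
trim_by_occupancy <- function(aln, min_occupancy) {
  stopifnot(inherits(aln, "codon_aln"))
  if (min_occupancy <= 0 || min_occupancy > 1)
    stop("min_occupancy must be in (0, 1]")
  occ <- column_occupancy(aln)
  keep <- occ >= min_occupancy
  if (!any(keep)) stop("alignment fully trimmed")
  out <- aln[, keep]
  attr(out, "removed_columns") <- which(!keep)
  out
}

#' Mask codon columns rare within a clade
#'
#' Removes codon columns occupied in strictly less than `min_frac` of the
#' named clade members (the 30% codon-occupancy rule applied before
#' branch-site selection scans; the rule is scoped to a clade, not the
#' full alignment).
#'
#' @param aln a [codon_aln].
#' @param clade_members character vector of sequence ids (non-empty,
#'   all present in the alignment).
#' @param min_frac occupancy bound (default 0.30); a column at exactly
#'   `min_frac` is retained.
#' @return masked `codon_aln` with attribute `removed_columns`.
#' @export
mask_rare_codon_columns <- function(aln, clade_members, min_frac = 0.30) {
  stopifnot(inherits(aln, "codon_aln"))
  if (length(clade_members) == 0) stop("clade is empty")
  occ <- column_occupancy(aln, rows = clade_members)
  keep <- occ >= min_frac
  if (!any(keep)) stop("alignment fully trimmed")
  out <- aln[, keep]
  attr(out, "removed_columns") <- which(!keep)
  out
}

#' Back-translate a protein alignment to codons
#'
#' Replaces each aligned residue with its source codon from the unaligned
#' CDS and each protein gap with `"---"`. A terminal stop codon on the
#' CDS is stripped (with a message); an internal stop or any
#' length/translation mismatch is an error naming the sequence and
#' position.
#'
#' @param protein_aln named character vector of aligned protein sequences
#'   (or a matrix of single residues).
#' @param cds_map named character vector: id -> unaligned CDS.
#' @return a [codon_aln].
#' @export
backtranslate <- function(protein_aln, cds_map) {
  if (is.matrix(protein_aln)) {
    protein_aln <- apply(protein_aln, 1L, paste0, collapse = "")
  }
  ids <- names(protein_aln)
  if (is.null(ids)) stop("protein alignment must be named")
  missing_cds <- setdiff(ids, names(cds_map))
  if (length(missing_cds) > 0)
    stop("no CDS for: ", paste(missing_cds, collapse = ", "))
  rows <- lapply(ids, function(id) {
    prot <- strsplit(toupper(protein_aln[[id]]), "")[[1]]
    cds <- toupper(cds_map[[id]])
    codons <- split_codons(cds)
    aas <- translate_codons(codons)
    if (length(aas) > 0 && aas[length(aas)] == "*") {
      message("stripping terminal stop codon from ", id)
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    if (any(aas == "*"))
      stop("internal stop codon in ", id, " at codon ", which(aas == "*")[1])
    res_pos <- which(prot != "-")
    if (length(res_pos) != length(codons))
      stop("CDS/protein length mismatch for ", id, ": ", length(codons),
           " codons vs ", length(res_pos), " residues")
    mism <- which(aas != prot[res_pos])
    if (length(mism) > 0)
      stop("CDS does not translate to protein for ", id, " at residue ",
           res_pos[mism[1]])
    out <- rep("---", length(prot))
    out[res_pos] <- codons
    out
  })
  lens <- unique(lengths(rows))
  if (length(lens) != 1L) stop("protein rows have unequal lengths")
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  codon_aln(m)
}
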