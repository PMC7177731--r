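# Shared codon machinery: the 61-state sense-codon space (universal code),
# the GY94-style rate matrix used both to simulate alignments and to compute
# branch-site likelihoods, and the codon_aln container.

#' Sense codons of the universal genetic code
#'
#' The 61 sense codons (stop codons TAA, TAG, TGA excluded), in alphabetical
#' order. This ordering defines the state space of the codon substitution
#' engine throughout the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

.CODONS <- NULL
.CODON_AA <- NULL

# lazily built lookup tables (avoids Biostrings calls at build time)
codon_tables <- function() {
  if (is.null(.CODONS)) {
    codons <- sense_codons()
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".CODONS", codons)
    utils::assignInMyNamespace(".CODON_AA", unname(gc[codons]))
  }
  list(codons = .CODONS, aa = .CODON_AA)
}

#' Translate a sense codon string to amino acids
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of one-letter amino acids ("*" for stop).
#' @keywords internal
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

is_stop_codon <- function(codons) {
  codons %in% c("TAA", "TAG", "TGA")
}

# split a DNA string into codons; no frame checking beyond length %% 3
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

.CODON_PAIRS <- NULL

# ordered pairs of sense codons one nucleotide apart, with transition /
# nonsynonymous flags; built once, drives rate-matrix construction
codon_pair_structure <- function() {
  if (is.null(.CODON_PAIRS)) {
    tab <- codon_tables()
    codons <- tab$codons
    aa <- tab$aa
    cm <- do.call(rbind, strsplit(codons, ""))
    transitions <- c(A = "G", G = "A", C = "T", T = "C")
    I <- integer(0); J <- integer(0); TI <- logical(0); NS <- logical(0)
    for (i in 1:61) {
      for (j in 1:61) {
        if (i == j) next
        diff <- which(cm[i, ] != cm[j, ])
        if (length(diff) != 1L) next
        I <- c(I, i); J <- c(J, j)
        TI <- c(TI, transitions[[cm[i, diff]]] == cm[j, diff])
        NS <- c(NS, aa[i] != aa[j])
      }
    }
    utils::assignInMyNamespace(".CODON_PAIRS",
                               list(I = I, J = J, TI = TI, NS = NS))
  }
  .CODON_PAIRS
}

#' GY94-style codon rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix of the Goldman-Yang-style
#' codon model: single-nucleotide changes only, target-codon frequency
#' `pi_j`, transition/transversion ratio `kappa` multiplying transitions
#' (A<->G, C<->T) and `omega` multiplying nonsynonymous changes. The matrix
#' is returned unscaled; see [codon_mixture_scale()].
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi numeric vector of 61 codon frequencies summing to 1.
#' @return 61x61 matrix with rows summing to zero.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L)
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  st <- codon_pair_structure()
  rate <- unname(pi[st$J]) * (1 + (kappa - 1) * st$TI) * (1 + (omega - 1) * st$NS)
  codons <- codon_tables()$codons
  Q <- matrix(0, 61L, 61L, dimnames = list(codons, codons))
  Q[cbind(st$I, st$J)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

#' Mean substitution rate of a site-class mixture
#'
#' Expected rate (substitutions per codon per unit time) of the unscaled
#' GY94 matrix averaged over site classes. Dividing branch lengths' rate
#' matrices by this value calibrates branch lengths to expected
#' substitutions per codon site under the mixture.
#'
#' @param kappa,pi as in [gy94_rate_matrix()].
#' @param omegas per-class dN/dS values.
#' @param props per-class proportions (sum to 1).
#' @return positive scalar.
#' @export
codon_mixture_scale <- function(kappa, pi, omegas, props) {
  stopifnot(length(omegas) == length(props), abs(sum(props) - 1) < 1e-6)
  st <- codon_pair_structure()
  base <- unname(pi[st$I] * pi[st$J]) * (1 + (kappa - 1) * st$TI)
  rates <- vapply(omegas, function(w)
    sum(base * (1 + (w - 1) * st$NS)), numeric(1))
  sum(rates * props)
}

# Reversible-matrix eigendecomposition: Q = D^{-1/2} (sym) D^{1/2}.
# Returns an object from which P(t) = exp(Qt) is cheap for any t.
codon_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  B <- (s * Q) %*% diag(1 / s)  # rows scaled by s, cols by 1/s
  B <- (B + t(B)) / 2           # symmetric up to rounding
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = (1 / s) * e$vectors,          # D^{-1/2} U
       right = t(e$vectors * s))            # U^T D^{1/2}
}

# P(t) from a codon_eigen decomposition; clamps tiny negatives.
codon_pmat <- function(dec, t) {
  P <- dec$left %*% (exp(dec$values * t) * dec$right)
  P[P < 0] <- 0
  P
}

#' Equal sense-codon frequencies
#' @return numeric vector of 61 values 1/61.
#' @export
equal_codon_freqs <- function() {
  p <- rep(1 / 61, 61L)
  names(p) <- codon_tables()$codons
  p
}

#' F3x4 codon frequencies from an alignment
#'
#' Empirical codon frequencies from per-position nucleotide frequencies
#' (the F3x4 convention), renormalized over the 61 sense codons.
#'
#' @param aln a [codon_aln] object.
#' @return named numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_codon_freqs <- function(aln) {
  stopifnot(inherits(aln, "codon_aln"))
  codons <- as.vector(unclass(aln))
  codons <- codons[!grepl("-", codons, fixed = TRUE)]
  if (length(codons) == 0L) stop("alignment contains no ungapped codons")
  m <- do.call(rbind, strsplit(codons, ""))
  freq <- lapply(1:3, function(k) {
    f <- table(factor(m[, k], levels = c("A", "C", "G", "T")))
    f <- as.numeric(f)
    if (sum(f) == 0) f <- rep(1, 4)
    f / sum(f)
  })
  tab <- codon_tables()
  cm <- do.call(rbind, strsplit(tab$codons, ""))
  idx <- function(x) match(x, c("A", "C", "G", "T"))
  p <- freq[[1]][idx(cm[, 1])] * freq[[2]][idx(cm[, 2])] * freq[[3]][idx(cm[, 3])]
  p <- p / sum(p)
  names(p) <- tab$codons
  p
}

# ---------------------------------------------------------------------------
# codon_aln container

#' Codon alignment container
#'
#' A codon alignment is stored as a character matrix with one row per
#' sequence and one column per codon; gap codons are `"---"`. Any codon
#' containing a gap character is treated as a gap for occupancy purposes.
#'
#' @param seqs named character vector of aligned nucleotide sequences of
#'   equal length divisible by 3, or a character matrix of codons.
#' @return object of class `codon_aln`.
#' @export
codon_aln <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must have unique names")
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("aligned sequences must have equal length")
    if (w %% 3L != 0L) stop("alignment length ", w, " is not a multiple of 3")
    m <- t(vapply(seqs, split_codons, character(w / 3L)))
    if (w / 3L == 1L) m <- matrix(m, ncol = 1L, dimnames = list(names(seqs), NULL))
  }
  m <- toupper(m)
  structure(m, class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("codon alignment: ", nrow(x), " sequences x ", ncol(x), " codons\n",
      sep = "")
  invisible(x)
}

#' @export
`[.codon_aln` <- function(x, i, j, ...) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, class = "codon_aln")
}

#' Number of codon columns / sequences
#' @param aln a `codon_aln`.
#' @return integer.
#' @export
n_codons <- function(aln) ncol(aln)

#' @rdname n_codons
#' @export
n_seqs <- function(aln) nrow(aln)

# TRUE where the codon contains a gap character
gap_mask <- function(aln) {
  matrix(grepl("-", unclass(aln), fixed = TRUE), nrow(aln), ncol(aln),
         dimnames = dimnames(aln))
}

#' Per-column occupancy of a codon alignment
#'
#' Fraction of rows with an ungapped codon in each column, optionally
#' restricted to a subset of sequences.
#'
#' @param aln a `codon_aln`.
#' @param rows optional character vector of sequence ids.
#' @return numeric vector over codon columns, values in \[0, 1\].
#' @export
column_occupancy <- function(aln, rows = NULL) {
  g <- gap_mask(aln)
  if (!is.null(rows)) {
    missing_ids <- setdiff(rows, rownames(aln))
    if (length(missing_ids) > 0)
      stop("ids not in alignment: ", paste(missing_ids, collapse = ", "))
    g <- g[rows, , drop = FALSE]
  }
  1 - colMeans(g)
}

#' Flatten a codon alignment to nucleotide strings
#' @param aln a `codon_aln`.
#' @return named character vector of aligned sequences.
#' @export
aln_to_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste0, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Read / write codon alignments as FASTA
#'
#' Thin wrappers over Biostrings FASTA IO that enforce codon framing.
#'
#' @param path file path.
#' @return `read_codon_alignment` returns a `codon_aln`.
#' @export
read_codon_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  codon_aln(stats::setNames(as.character(x), names(x)))
}

#' @rdname read_codon_alignment
#' @param aln a `codon_aln` to write.
#' @export
write_codon_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln_to_strings(aln))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Translate the ungapped rows of a codon alignment
#'
#' @param aln a `codon_aln`.
#' @return named character vector of protein sequences (gaps removed first).
#' @export
translate_alignment_rows <- function(aln) {
  s <- aln_to_strings(aln)
  vapply(s, function(x) {
    x <- gsub("-", "", x, fixed = TRUE)
    if (nchar(x) == 0L) return("")
    paste0(translate_codons(split_codons(x)), collapse = "")
  }, character(1))
}
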