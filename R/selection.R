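# Selection-pressure analysis: pairwise Ka/Ks by Nei-Gojobori (1986)
# counting with Jukes-Cantor correction, and the branch-site likelihood
# ratio test of episodic positive selection (model-A parameterization,
# naive empirical Bayes site identification).

# ---------------------------------------------------------------------------
# NG86 counting tables (built lazily, shared by all calls)

.NG86 <- NULL

# per-codon synonymous site counts and 61x61 average synonymous /
# nonsynonymous step counts over shortest mutational pathways (paths
# through stop codons excluded; changes to stops count as nonsynonymous
# in site counting so that N + S = 3L holds exactly)
ng86_tables <- function() {
  if (!is.null(.NG86)) return(.NG86)
  tab <- codon_tables()
  codons <- tab$codons
  aa <- tab$aa
  nt <- c("A", "C", "G", "T")
  cm <- do.call(rbind, strsplit(codons, ""))
  gc_all <- Biostrings::GENETIC_CODE

  syn_sites <- numeric(61)
  for (i in 1:61) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(nt, cm[i, pos])) {
        mut <- cm[i, ]
        mut[pos] <- b
        mut <- paste0(mut, collapse = "")
        if (gc_all[[mut]] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  SD <- matrix(0, 61, 61)
  ND <- matrix(0, 61, 61)
  for (i in 1:61) {
    for (j in 1:61) {
      if (i >= j) next
      diff <- which(cm[i, ] != cm[j, ])
      d <- length(diff)
      if (d == 0) next
      P <- perms[[as.character(d)]]
      count_path <- function(ord, allow_stops) {
        cur <- cm[i, ]
        sd <- 0; nd <- 0
        for (pos in diff[ord]) {
          prev <- paste0(cur, collapse = "")
          cur[pos] <- cm[j, pos]
          nxt <- paste0(cur, collapse = "")
          if (!allow_stops && gc_all[[nxt]] == "*" && nxt != codons[j])
            return(NULL)
          if (gc_all[[prev]] == gc_all[[nxt]] && gc_all[[nxt]] != "*")
            sd <- sd + 1 else nd <- nd + 1
        }
        c(sd, nd)
      }
      res <- lapply(seq_len(nrow(P)), function(r)
        count_path(P[r, ], allow_stops = FALSE))
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res) == 0)
        res <- lapply(seq_len(nrow(P)), function(r)
          count_path(P[r, ], allow_stops = TRUE))
      m <- do.call(rbind, res)
      SD[i, j] <- SD[j, i] <- mean(m[, 1])
      ND[i, j] <- ND[j, i] <- mean(m[, 2])
    }
  }
  out <- list(syn_sites = syn_sites, SD = SD, ND = ND)
  utils::assignInMyNamespace(".NG86", out)
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Synonymous/nonsynonymous site fractions are computed per codon
#' (changes to stop codons count as nonsynonymous, so `N + S` equals 3
#' times the compared codon count exactly) and averaged over the two
#' sequences. Codon differences are resolved by averaging
#' synonymous/nonsynonymous step counts over all shortest mutational
#' pathways, excluding pathways through stop codons (relaxed only if
#' every pathway is blocked). Proportions are corrected with the
#' Jukes-Cantor formula `d = -(3/4) log(1 - (4/3) p)`; a proportion at or
#' beyond 3/4 is saturated and reported as `NA` with a flag.
#'
#' Codon positions where either sequence has a gap are removed pairwise.
#' The ratio is `NA` when `Ks` is zero (e.g. identical sequences).
#'
#' @param cds1,cds2 in-frame nucleotide strings of equal length, or
#'   character vectors of codons.
#' @return object of class `kaks_result`: list with Ka, Ks, ratio, N, S,
#'   Nd, Sd, pN, pS, n_codons, saturated.
#' @export
ng86_kaks <- function(cds1, cds2) {
  to_codons <- function(x) if (length(x) == 1L) split_codons(toupper(x)) else
    toupper(x)
  c1 <- to_codons(cds1)
  c2 <- to_codons(cds2)
  if (length(c1) != length(c2))
    stop("sequences differ in length: ", length(c1), " vs ", length(c2),
         " codons")
  gap <- grepl("-", c1, fixed = TRUE) | grepl("-", c2, fixed = TRUE)
  c1 <- c1[!gap]; c2 <- c2[!gap]
  if (any(is_stop_codon(c1)) || any(is_stop_codon(c2)))
    stop("internal stop codon in input")
  tab <- codon_tables()
  i1 <- match(c1, tab$codons)
  i2 <- match(c2, tab$codons)
  if (anyNA(i1) || anyNA(i2)) stop("non-ACGT codon in input")
  ng <- ng86_tables()
  L <- length(i1)
  S <- (sum(ng$syn_sites[i1]) + sum(ng$syn_sites[i2])) / 2
  N <- 3 * L - S
  Sd <- sum(ng$SD[cbind(i1, i2)])
  Nd <- sum(ng$ND[cbind(i1, i2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ka <- jc(pN)
  Ks <- jc(pS)
  saturated <- c(Ka = pN >= 0.75, Ks = pS >= 0.75)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio, N = N, S = S, Nd = Nd,
                 Sd = Sd, pN = pN, pS = pS, n_codons = L,
                 saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%d codons)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$n_codons))
  invisible(x)
}

#' Ka/Ks over a list of sequence pairs from an alignment
#'
#' Applies [ng86_kaks()] to each pair of alignment rows (gaps removed
#' pairwise) and attaches a selection-regime classification: purifying
#' below `bands[1]`, positive above `bands[2]`, neutral between.
#'
#' @param aln a [codon_aln].
#' @param pairs 2-column matrix or data.frame of sequence ids.
#' @param bands classification thresholds (defaults 0.5 and 1.5).
#' @return data.frame: id1, id2, Ka, Ks, ratio, class.
#' @export
kaks_pair_table <- function(aln, pairs, bands = c(0.5, 1.5)) {
  stopifnot(inherits(aln, "codon_aln"))
  pairs <- as.matrix(pairs)
  missing_ids <- setdiff(unique(as.vector(pairs)), rownames(aln))
  if (length(missing_ids) > 0)
    stop("pair ids not in alignment: ", paste(missing_ids, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    r <- ng86_kaks(unclass(aln)[pairs[k, 1], ], unclass(aln)[pairs[k, 2], ])
    cls <- if (is.na(r$ratio)) NA_character_
      else if (r$ratio < bands[1]) "purifying"
      else if (r$ratio > bands[2]) "positive" else "neutral"
    data.frame(id1 = pairs[k, 1], id2 = pairs[k, 2], Ka = r$Ka, Ks = r$Ks,
               ratio = r$ratio, class = cls)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Branch-site model (model-A parameterization)

#' Branch-site codon model specification
#'
#' Model-A site classes: class 0 (`omega0` in (0, 1\]) and class 1
#' (neutral) behave identically on every branch; classes 2a and 2b take
#' `omega2` on the foreground branches and behave like classes 0 and 1
#' respectively on the background. Proportions satisfy
#' `p2a/p2b = p0/p1`. The null model fixes `omega2 = 1` and is nested in
#' the alternative.
#'
#' @param kappa transition/transversion ratio.
#' @param omega0 purifying-class dN/dS in (0, 1\].
#' @param omega2 foreground dN/dS (>= 1; 1 gives the null model).
#' @param p0,p1 proportions of classes 0 and 1 (p0 + p1 <= 1).
#' @param pi codon frequencies (61-vector); default equal.
#' @param foreground character vector of foreground branch ids (labels
#'   of the nodes below those branches).
#' @return object of class `branch_site_model`.
#' @export
branch_site_model <- function(kappa, omega0, omega2 = 1, p0, p1,
                              pi = NULL, foreground = character(0)) {
  if (is.null(pi)) pi <- equal_codon_freqs()
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega0 <= 0 || omega0 > 1) stop("omega0 must be in (0, 1]")
  if (omega2 < 1) stop("omega2 must be >= 1")
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-9) stop("invalid proportions")
  if (p0 + p1 <= 0) stop("p0 + p1 must be positive")
  p2 <- max(0, 1 - p0 - p1)
  props <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  structure(list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1, props = props, pi = pi,
                 foreground = foreground,
                 bg_omegas = c(omega0, 1, omega0, 1),
                 fg_omegas = c(omega0, 1, omega2, omega2)),
            class = "branch_site_model")
}

# tree/alignment indexing reused across likelihood evaluations
lik_cache <- function(tree, aln) {
  stopifnot(inherits(aln, "codon_aln"))
  tab <- codon_tables()
  if (is.character(tree) && length(tree) == 1L) {
    if (!tree %in% rownames(aln)) stop("sequence ", tree, " not in alignment")
    st <- match(unclass(aln)[tree, ], tab$codons)
    return(list(single = TRUE, states = st))
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, rownames(aln))
  if (length(missing_tips) > 0)
    stop("tree tips not in alignment: ", paste(missing_tips, collapse = ", "))
  n_tip <- length(tips)
  labs <- node_labels(tree)
  if (is.null(tree$node.label)) labs <- c(tips, paste0("n", seq_len(tree$Nnode)))
  states <- t(vapply(tips, function(id)
    match(unclass(aln)[id, ], tab$codons), integer(ncol(aln))))
  if (ncol(aln) == 1L) states <- matrix(states, ncol = 1L)
  depth <- node_depths_topo(tree)
  eord <- order(depth[tree$edge[, 2]], decreasing = TRUE)  # deepest first
  states0 <- states
  states0[is.na(states0)] <- 0L
  storage.mode(states0) <- "integer"
  list(single = FALSE, tree = tree, n_tip = n_tip, labs = labs,
       states = states, states0 = states0, n_sites = ncol(aln),
       eord = eord, root = n_tip + 1L,
       n_node = n_tip + tree$Nnode,
       edge_child = tree$edge[, 2], edge_parent = tree$edge[, 1],
       edge_len = tree$edge.length)
}

# eigendecompositions of unscaled GY94 matrices, cached by (kappa,
# omega); the mixture scale is applied to branch lengths instead, so the
# cache stays valid while proportions change during optimization
.DEC_CACHE <- NULL

dec_cache_get <- function(kappa, omega, pi) {
  if (is.null(.DEC_CACHE))
    utils::assignInMyNamespace(".DEC_CACHE", new.env(parent = emptyenv()))
  cache <- .DEC_CACHE
  fp <- paste0(format(sum(pi * seq_along(pi)), digits = 17), "|",
               format(pi[1], digits = 17))
  if (!identical(cache$pi_fingerprint, fp)) {
    rm(list = ls(cache), envir = cache)
    cache$pi_fingerprint <- fp
  }
  key <- sprintf("%.17g|%.17g", kappa, omega)
  d <- cache[[key]]
  if (is.null(d)) {
    if (length(ls(cache)) > 400L) {
      rm(list = setdiff(ls(cache), "pi_fingerprint"), envir = cache)
      cache$pi_fingerprint <- fp
    }
    d <- codon_eigen(gy94_rate_matrix(kappa, omega, pi), pi)
    cache[[key]] <- d
  }
  d
}

# full mixture log-likelihood; returns per-class site likelihood matrix
# when per_site = TRUE
bs_loglik <- function(cache, model, per_site = FALSE) {
  pi <- model$pi
  if (isTRUE(cache$single)) {
    ll <- sum(log(pi[cache$states]))
    if (!per_site) return(ll)
    return(list(lnL = ll, site_class_loglik = NULL))
  }
  scale <- codon_mixture_scale(model$kappa, pi, model$bg_omegas, model$props)
  uw <- unique(c(model$bg_omegas, model$fg_omegas))
  decs <- lapply(uw, function(w) dec_cache_get(model$kappa, w, pi))
  fg_edge <- cache$labs[cache$edge_child] %in% model$foreground
  eord <- cache$eord
  widx <- matrix(0L, 4L, length(eord))
  for (cl in 1:4) {
    wbg <- match(model$bg_omegas[cl], uw)
    wfg <- match(model$fg_omegas[cl], uw)
    widx[cl, ] <- ifelse(fg_edge[eord], wfg, wbg)
  }
  cls_ll <- .bs_class_logliks(cache$edge_child[eord],
                              cache$edge_parent[eord],
                              cache$n_tip, cache$n_node, cache$states0,
                              decs, cache$edge_len[eord], scale, widx,
                              unname(pi), cache$root)
  mx <- pmax(cls_ll[1, ], cls_ll[2, ], cls_ll[3, ], cls_ll[4, ])
  site_ll <- mx + log(.colSums(model$props * exp(cls_ll - rep(mx, each = 4L)),
                               4L, cache$n_sites))
  lnL <- sum(site_ll)
  if (!per_site) return(lnL)
  list(lnL = lnL, site_class_loglik = cls_ll, props = model$props)
}

#' Log-likelihood of a codon alignment under a branch-site model
#'
#' GY94-style 61-state rate matrices per site class (scaled so the
#' background mixture has mean rate 1), Felsenstein pruning per site,
#' mixed over the four model-A classes. Branch lengths are expected
#' substitutions per codon site. A single sequence (tree given as its
#' id) has `lnL = sum(log pi(codon))`.
#'
#' @param tree rooted `ape::phylo` whose tips are alignment rows, or a
#'   single sequence id.
#' @param aln a [codon_aln].
#' @param model a [branch_site_model()].
#' @return scalar log-likelihood.
#' @export
codon_loglikelihood <- function(tree, aln, model) {
  stopifnot(inherits(model, "branch_site_model"))
  cache <- lik_cache(tree, aln)
  ll <- bs_loglik(cache, model)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Branch-site likelihood ratio test of episodic positive selection
#'
#' Fits the null (`omega2 = 1`) and alternative (`omega2 >= 1` free)
#' branch-site models by bounded quasi-Newton optimization of
#' `(kappa, omega0, p0, p1)` (+ `omega2`), compares them with a
#' chi-square test on one degree of freedom (statistic clamped at zero),
#' and, when significant, reports naive-empirical-Bayes posterior
#' probabilities of the positively selected classes per site.
#'
#' Branch lengths are taken from the tree and held fixed for both
#' hypotheses (set `estimate_scale = TRUE` to first fit a global
#' branch-length scale under a single-class model). The alternative fit
#' is warm-started from the null fit; additional seeded starts can be
#' requested via `n_starts`.
#'
#' @param tree rooted `ape::phylo` with branch lengths in expected
#'   substitutions per codon site.
#' @param aln a [codon_aln] (typically after [mask_rare_codon_columns()]).
#' @param foreground foreground branch id(s): labels of the nodes below
#'   the foreground branches.
#' @param alpha significance level (default 0.05).
#' @param codon_freqs `"equal"` or `"f3x4"` (empirical, the default).
#' @param neb_threshold posterior probability threshold for reporting
#'   sites (default 0.95).
#' @param n_starts number of optimization starts (default 1; the
#'   alternative model is additionally warm-started from the null fit).
#' @param estimate_scale optimize a global branch-length scale factor
#'   under a single-class model first (default FALSE).
#' @param seed integer seed for the jittered extra starts.
#' @return object of class `lrt_outcome`: list with lnL_null, lnL_alt,
#'   statistic, p_value, significant, neb_sites (data.frame site,
#'   posterior), null_fit, alt_fit.
#' @export
branch_site_test <- function(tree, aln, foreground, alpha = 0.05,
                             codon_freqs = c("f3x4", "equal"),
                             neb_threshold = 0.95, n_starts = 1L,
                             estimate_scale = FALSE, seed = 1L) {
  codon_freqs <- match.arg(codon_freqs)
  pi <- if (codon_freqs == "f3x4") f3x4_codon_freqs(aln) else
    equal_codon_freqs()
  cache <- lik_cache(tree, aln)
  if (isTRUE(cache$single)) stop("branch-site test needs a multi-tip tree")
  if (!any(cache$labs[cache$edge_child] %in% foreground))
    stop("foreground branch not found: ", paste(foreground, collapse = ", "))

  if (estimate_scale) {
    # single-class fit of (kappa, omega, scale); rescales branch lengths
    obj0 <- function(p) {
      m <- branch_site_model(kappa = p[1], omega0 = min(p[2], 1),
                             omega2 = max(p[2], 1), p0 = 1 - 1e-6,
                             p1 = 1e-6, pi = pi)
      m$bg_omegas <- rep(p[2], 4); m$fg_omegas <- rep(p[2], 4)
      cache2 <- cache
      cache2$edge_len <- cache$edge_len * p[3]
      -bs_loglik(cache2, m)
    }
    f0 <- stats::nlminb(c(2, 0.3, 1), obj0,
                        lower = c(0.1, 1e-4, 1e-3),
                        upper = c(40, 5, 100),
                        control = list(rel.tol = 1e-8, eval.max = 400L))
    cache$edge_len <- cache$edge_len * f0$par[3]
  }

  mk <- function(p, null) {
    P01 <- p[3]; f0 <- p[4]
    branch_site_model(kappa = p[1], omega0 = p[2],
                      omega2 = if (null) 1 else p[5],
                      p0 = P01 * f0, p1 = P01 * (1 - f0), pi = pi,
                      foreground = foreground)
  }
  obj <- function(p, null) -bs_loglik(cache, mk(p, null))
  lower <- c(0.1, 1e-4, 0.01, 1e-3)
  upper <- c(40, 1, 1, 1 - 1e-3)
  start0 <- c(2, 0.2, 0.9, 0.7)

  fit_model <- function(null, starts) {
    best <- NULL
    for (s in starts) {
      lo <- if (null) lower else c(lower, 1)
      hi <- if (null) upper else c(upper, 100)
      f <- stats::nlminb(s, obj, null = null, lower = lo, upper = hi,
                         control = list(rel.tol = 1e-8, eval.max = 500L,
                                        iter.max = 300L))
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    if (!is.finite(best$objective))
      stop("optimizer failed: non-finite objective")
    best
  }

  starts_null <- list(start0)
  if (n_starts > 1L) {
    set.seed(derive_seed(seed, "bs-starts"))
    for (k in seq_len(n_starts - 1L))
      starts_null <- c(starts_null, list(c(
        stats::runif(1, 1, 6), stats::runif(1, 0.02, 0.8),
        stats::runif(1, 0.5, 0.99), stats::runif(1, 0.3, 0.9))))
  }
  null_fit <- fit_model(TRUE, starts_null)
  starts_alt <- c(list(c(null_fit$par, 2.5)),
                  lapply(starts_null[-1], function(s) c(s, 3)))
  alt_fit <- fit_model(FALSE, starts_alt)

  lnL_null <- -null_fit$objective
  lnL_alt <- max(-alt_fit$objective, lnL_null)  # nesting after clamping
  statistic <- max(0, 2 * (lnL_alt - lnL_null))
  p_value <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  significant <- p_value <= alpha

  neb <- data.frame(site = integer(0), posterior = numeric(0))
  alt_model <- mk(alt_fit$par, null = FALSE)
  ps <- bs_loglik(cache, alt_model, per_site = TRUE)
  if (!is.null(ps$site_class_loglik)) {
    cl <- ps$site_class_loglik
    mx <- apply(cl, 2L, max)
    w <- alt_model$props * exp(cl - rep(mx, each = 4L))
    post2 <- colSums(w[3:4, , drop = FALSE]) / colSums(w)
    if (significant) {
      sel <- which(post2 >= neb_threshold)
      neb <- data.frame(site = sel, posterior = post2[sel])
    }
    attr(neb, "posterior_all") <- post2
  }
  structure(list(lnL_null = lnL_null, lnL_alt = lnL_alt,
                 statistic = statistic, p_value = p_value,
                 significant = significant, alpha = alpha,
                 neb_sites = neb, null_fit = null_fit, alt_fit = alt_fit,
                 foreground = foreground),
            class = "lrt_outcome")
}

#' @export
print.lrt_outcome <- function(x, ...) {
  cat(sprintf(
    "branch-site LRT: 2*dlnL = %.4f, p = %.4g (%ssignificant at %.2g)\n",
    x$statistic, x$p_value, if (x$significant) "" else "not ", x$alpha))
  if (nrow(x$neb_sites) > 0)
    cat("NEB sites >= threshold: ", paste(x$neb_sites$site, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Parse a Newick string with `#1` foreground tags
#'
#' Branch labels suffixed with `#1` (the common branch-site dialect) mark
#' foreground branches; the suffix is stripped from the returned tree.
#'
#' @param text Newick string.
#' @return list with `tree` (`ape::phylo`) and `foreground` (character).
#' @export
parse_foreground_newick <- function(text) {
  text2 <- gsub("#1", "__FG__", text, fixed = TRUE)
  tree <- ape::read.tree(text = text2)
  if (is.null(tree)) stop("could not parse Newick string")
  fg <- character(0)
  strip <- function(labs) {
    hit <- grepl("__FG__$", labs)
    fg <<- c(fg, sub("__FG__$", "", labs[hit]))
    sub("__FG__$", "", labs)
  }
  tree$tip.label <- strip(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- strip(tree$node.label)
  list(tree = tree, foreground = fg)
}
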