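# Droplet digital PCR quantification: the fraction of negative droplets
# estimates the Poisson zero class, lambda = -ln(n_negative/n_total)
# template copies per droplet; gene copy number is the target/reference
# concentration ratio.

#' Droplet assay counts
#'
#' @param n_total accepted droplets (>= 1).
#' @param n_negative droplets without amplification (0..n_total).
#' @param target amplicon label.
#' @param droplet_volume_nl optional droplet volume in nanoliters;
#'   enables copies-per-microliter reporting.
#' @return object of class `droplet_assay`.
#' @export
droplet_assay <- function(n_total, n_negative, target = "target",
                          droplet_volume_nl = NULL) {
  n_total <- as.integer(n_total)
  n_negative <- as.integer(n_negative)
  if (n_total < 1L) stop("n_total must be >= 1")
  if (n_negative < 0L || n_negative > n_total)
    stop("n_negative must be in [0, n_total]")
  structure(list(n_total = n_total, n_negative = n_negative,
                 target = target, droplet_volume_nl = droplet_volume_nl),
            class = "droplet_assay")
}

#' @export
print.droplet_assay <- function(x, ...) {
  cat(sprintf("ddPCR assay '%s': %d/%d droplets negative\n", x$target,
              x$n_negative, x$n_total), sep = "")
  invisible(x)
}

#' Poisson concentration of a droplet assay
#'
#' `lambda = -ln(n_negative/n_total)` mean template copies per droplet.
#' The default 95% interval propagates the binomial error of the
#' negative fraction through the log transform (delta method);
#' `method = "clopper-pearson"` uses the exact binomial interval
#' instead. All droplets positive is a saturation error (dilute the
#' template); all negative gives `lambda = 0` with a one-sided upper
#' bound.
#'
#' @param assay a [droplet_assay()].
#' @param conf confidence level (default 0.95).
#' @param method `"delta"` or `"clopper-pearson"`.
#' @return list: lambda, ci (length-2), n_total, n_negative, and
#'   copies_per_ul when droplet volume metadata is present.
#' @export
poisson_concentration <- function(assay, conf = 0.95,
                                  method = c("delta", "clopper-pearson")) {
  stopifnot(inherits(assay, "droplet_assay"))
  method <- match.arg(method)
  n <- assay$n_total
  neg <- assay$n_negative
  if (neg == 0L)
    stop("all droplets positive: assay saturated, dilute the template")
  alpha <- 1 - conf
  if (neg == n) {
    # one-sided: lambda = 0, upper bound from P(all negative) = p^n
    p_lo <- alpha^(1 / n)
    out <- list(lambda = 0, ci = c(0, -log(p_lo)))
  } else {
    p <- neg / n
    if (method == "delta") {
      z <- stats::qnorm(1 - alpha / 2)
      se_p <- sqrt(p * (1 - p) / n)
      lo_p <- max(p - z * se_p, 1e-12)
      hi_p <- min(p + z * se_p, 1 - 1e-12)
    } else {
      ci_p <- stats::binom.test(neg, n, conf.level = conf)$conf.int
      lo_p <- ci_p[1]; hi_p <- ci_p[2]
    }
    out <- list(lambda = -log(p), ci = c(-log(hi_p), -log(lo_p)))
  }
  out$n_total <- n
  out$n_negative <- neg
  if (!is.null(assay$droplet_volume_nl)) {
    out$copies_per_ul <- out$lambda / assay$droplet_volume_nl * 1000
  }
  out
}

#' Reference-normalized gene copy number from paired assays
#'
#' `copy number = lambda_target / lambda_reference x reference_copies`.
#' The interval combines the relative errors of both concentrations on
#' the log scale (delta method).
#'
#' @param target,reference [droplet_assay()] objects from the same
#'   dilution (apply `dilution_ratio` when they differ).
#' @param reference_copies copies of the reference locus per genome
#'   (default 1).
#' @param dilution_ratio target dilution / reference dilution (default 1).
#' @param conf confidence level (default 0.95).
#' @return list: ratio, ci (length-2), lambda_target, lambda_reference.
#' @export
copy_number <- function(target, reference, reference_copies = 1L,
                        dilution_ratio = 1, conf = 0.95) {
  qt <- poisson_concentration(target, conf = conf)
  qr <- poisson_concentration(reference, conf = conf)
  if (qr$lambda == 0) stop("reference concentration is zero")
  ratio <- qt$lambda / qr$lambda * reference_copies / dilution_ratio
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rel_se <- function(assay, q) {
    if (q$lambda == 0) return(0)
    p <- assay$n_negative / assay$n_total
    se_p <- sqrt(p * (1 - p) / assay$n_total)
    (se_p / p) / q$lambda        # sd of lambda over lambda
  }
  v <- rel_se(target, qt)^2 + rel_se(reference, qr)^2
  ci <- ratio * exp(c(-1, 1) * z * sqrt(v))
  list(ratio = ratio, ci = ci,
       lambda_target = qt$lambda, lambda_reference = qr$lambda)
}
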