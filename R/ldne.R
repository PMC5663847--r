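#' @name ldne
#' @title Contemporary effective population size from linkage
#'   disequilibrium
#' @description The Burrows composite-disequilibrium estimator of
#'   contemporary Ne under random mating: inter-locus allele associations
#'   in a closed population reflect drift in a finite number of breeders,
#'   so the mean squared correlation `r^2` in excess of its sampling
#'   expectation estimates 1/(3 Ne) (with the published second-order bias
#'   corrections). Rare alleles below a critical frequency are screened
#'   out before pairing.
NULL

#' Burrows composite disequilibrium and r-squared per allele pair
#'
#' For every inter-locus allele pair whose frequencies both lie strictly
#' inside `(p_crit, 1 - p_crit)` among the individuals typed at both loci
#' (the screen is symmetric: the complement of a rare allele carries the
#' same disequilibrium information): the composite disequilibrium
#' `D = (S/(S-1)) (sum_i X_i Y_i / (2S) - 2 p q)`, with `X_i`, `Y_i` the
#' per-individual dosages (0/1/2) of the two alleles, and
#' `r^2 = D^2 / (p(1-p) q(1-q))`. Within-locus allele pairs are never
#' compared.
#'
#' @param geno A [genotype_table()] restricted to one population.
#' @param p_crit Minimum allele frequency (default 0.02).
#' @return Data frame: `locus1`, `locus2`, `allele1`, `allele2`, `S`
#'   (individuals typed at both loci), `D`, `r2`.
#' @export
burrows_r2 <- function(geno, p_crit = 0.02) {
  stopifnot(p_crit >= 0, p_crit < 0.5)
  L <- length(geno$loci)
  if (L < 2) stop("at least 2 loci are required")
  rows <- list()
  for (l1 in seq_len(L - 1)) {
    for (l2 in (l1 + 1):L) {
      both <- !is.na(geno$a1[, l1]) & !is.na(geno$a1[, l2])
      S <- sum(both)
      if (S < 2) next
      x1 <- geno$a1[both, l1]; x2 <- geno$a2[both, l1]
      y1 <- geno$a1[both, l2]; y2 <- geno$a2[both, l2]
      al1 <- sort(unique(c(x1, x2)))
      al2 <- sort(unique(c(y1, y2)))
      for (a in al1) {
        p <- (sum(x1 == a) + sum(x2 == a)) / (2 * S)
        # symmetric screen: a near-fixed allele is the mirror of a rare one
        if (p <= p_crit || p >= 1 - p_crit) next
        X <- (x1 == a) + (x2 == a)
        for (b in al2) {
          q <- (sum(y1 == b) + sum(y2 == b)) / (2 * S)
          if (q <= p_crit || q >= 1 - p_crit) next
          Y <- (y1 == b) + (y2 == b)
          D <- S / (S - 1) * (sum(X * Y) / (2 * S) - 2 * p * q)
          r2 <- D^2 / (p * (1 - p) * q * (1 - q))
          rows[[length(rows) + 1]] <-
            data.frame(locus1 = geno$loci[l1], locus2 = geno$loci[l2],
                       allele1 = a, allele2 = b, S = S, D = D, r2 = r2,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    stop("estimation error: no usable allele pairs after screening")
  do.call(rbind, rows)
}

# Waples (2006) sampling expectation and bias-corrected Ne, random mating
.e_r2_sample <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

.ne_from_r2prime <- function(r2p, S) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) return(Inf)
    ne <- (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) return(Inf)
    ne <- (0.308 + sqrt(disc)) / (2 * r2p)
  }
  if (ne <= 0) Inf else ne
}

#' LD-based estimate of contemporary Ne
#'
#' Weighted mean `r^2` over screened allele pairs (weights = pair sample
#' size `S`), harmonic mean `S`, subtraction of the sampling expectation
#' `E[r^2]` for that sample size, and conversion to Ne with the
#' bias-corrected random-mating formula; a non-positive drift component
#' yields `Ne = Inf`. Confidence intervals are produced both
#' parametrically (chi-squared on the number of allele-pair comparisons)
#' and by jackknifing loci.
#'
#' @param geno A [genotype_table()] restricted to one population.
#' @param p_crit Minimum allele frequency (default 0.02).
#' @return An object of class `ne_estimate`: `ne`, `r2_mean`, `r2_drift`,
#'   `e_r2_sample`, `harmonic_s`, `n_comparisons`, `ci_parametric`,
#'   `ci_jackknife`.
#' @export
ldne_estimate <- function(geno, p_crit = 0.02) {
  pairs <- burrows_r2(geno, p_crit)
  est <- .ldne_from_pairs(pairs)
  # parametric CI: chi-squared on the comparison count
  n_cmp <- nrow(pairs)
  r2_lo <- n_cmp * est$r2_mean / qchisq(0.975, n_cmp)
  r2_hi <- n_cmp * est$r2_mean / qchisq(0.025, n_cmp)
  ci_par <- c(.ne_from_r2prime(r2_hi - est$e_r2, est$harmonic_s),
              .ne_from_r2prime(r2_lo - est$e_r2, est$harmonic_s))
  ci_par <- sort(ci_par)
  # jackknife over loci: chi-squared CI with the effective degrees of
  # freedom implied by the jackknife variance of the mean r2
  loci <- unique(c(pairs$locus1, pairs$locus2))
  ci_jack <- c(NA_real_, NA_real_)
  if (length(loci) > 2) {
    pseudo <- vapply(loci, function(l) {
      keep <- pairs$locus1 != l & pairs$locus2 != l
      if (!any(keep)) return(NA_real_)
      weighted.mean(pairs$r2[keep], pairs$S[keep])
    }, numeric(1))
    pseudo <- pseudo[is.finite(pseudo)]
    g <- length(pseudo)
    if (g > 2) {
      jk_var <- (g - 1) / g * sum((pseudo - mean(pseudo))^2)
      if (jk_var > 0) {
        n_eff <- max(1, 2 * est$r2_mean^2 / jk_var)
        r2_jlo <- n_eff * est$r2_mean / qchisq(0.975, n_eff)
        r2_jhi <- n_eff * est$r2_mean / qchisq(0.025, n_eff)
        ci_jack <- sort(c(
          .ne_from_r2prime(r2_jhi - est$e_r2, est$harmonic_s),
          .ne_from_r2prime(r2_jlo - est$e_r2, est$harmonic_s)))
      }
    }
  }
  structure(c(est, list(n_comparisons = n_cmp, ci_parametric = ci_par,
                        ci_jackknife = ci_jack, p_crit = p_crit)),
            class = "ne_estimate")
}

.ldne_from_pairs <- function(pairs) {
  r2_mean <- weighted.mean(pairs$r2, pairs$S)
  harmonic_s <- nrow(pairs) / sum(1 / pairs$S)
  e_r2 <- .e_r2_sample(harmonic_s)
  r2_drift <- r2_mean - e_r2
  list(ne = .ne_from_r2prime(r2_drift, harmonic_s), r2_mean = r2_mean,
       r2_drift = r2_drift, e_r2 = e_r2, harmonic_s = harmonic_s)
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.0f", v), "Inf")
  cat("LD-Ne estimate:", fmt(x$ne), "\n")
  cat("  parametric 95% CI: [", fmt(x$ci_parametric[1]), "-",
      fmt(x$ci_parametric[2]), "]\n")
  cat("  jackknife 95% CI: [", fmt(x$ci_jackknife[1]), "-",
      fmt(x$ci_jackknife[2]), "]\n")
  cat("  mean r2 =", signif(x$r2_mean, 4), "over", x$n_comparisons,
      "allele pairs; harmonic S =", sprintf("%.1f", x$harmonic_s), "\n")
  invisible(x)
}

#' Forward Wright-Fisher sampler for LD-Ne validation
#'
#' Discrete-generation random-mating Wright-Fisher population of `n_e`
#' diploids with unlinked stepwise-mutating loci; after `n_generations`
#' (enough for drift LD to equilibrate at the `1/(3Ne)` level) a random
#' sample of individuals is genotyped. This forward sampler generates the
#' multilocus drift disequilibrium that independent-locus coalescent
#' genealogies by construction do not carry, so it is the generating model
#' for LD-Ne recovery checks.
#'
#' @param n_e True diploid effective (census) size.
#' @param n_sample Individuals sampled (<= `n_e`).
#' @param n_loci Number of unlinked loci.
#' @param n_generations Generations simulated (default 30).
#' @param init_alleles Number of equally frequent starting alleles.
#' @param mu Stepwise mutation rate per copy per generation.
#' @param seed Optional integer seed.
#' @return A [genotype_table()].
#' @export
simulate_wright_fisher <- function(n_e, n_sample, n_loci,
                                   n_generations = 30, init_alleles = 8,
                                   mu = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_sample <= n_e)
  a1 <- matrix(sample.int(init_alleles, n_e * n_loci, TRUE) + 20L,
               n_e, n_loci)
  a2 <- matrix(sample.int(init_alleles, n_e * n_loci, TRUE) + 20L,
               n_e, n_loci)
  for (g in seq_len(n_generations)) {
    mo <- sample.int(n_e, n_e, TRUE)
    fa <- sample.int(n_e, n_e, TRUE)
    n1 <- matrix(0L, n_e, n_loci); n2 <- n1
    for (l in seq_len(n_loci)) {
      n1[, l] <- ifelse(runif(n_e) < 0.5, a1[mo, l], a2[mo, l])
      n2[, l] <- ifelse(runif(n_e) < 0.5, a1[fa, l], a2[fa, l])
    }
    if (mu > 0) {
      for (m in list(quote(n1), quote(n2))) {
        x <- eval(m)
        hit <- which(runif(length(x)) < mu)
        if (length(hit)) {
          x[hit] <- pmax(2L, x[hit] +
                           sample(c(-1L, 1L), length(hit), TRUE))
          if (identical(m, quote(n1))) n1 <- x else n2 <- x
        }
      }
    }
    a1 <- n1; a2 <- n2
  }
  keep <- sample.int(n_e, n_sample)
  genotype_table(sprintf("ind%03d", seq_len(n_sample)),
                 sprintf("locus%02d", seq_len(n_loci)),
                 a1[keep, , drop = FALSE], a2[keep, , drop = FALSE])
}
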