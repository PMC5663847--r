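#' @name microsat-diversity
#' @title Microsatellite diversity and differentiation statistics
#' @description Per-population diversity summaries (observed and expected
#'   heterozygosity, Weir-Cockerham F_IS with a permutation test, rarefied
#'   and private allelic richness, the Garza-Williamson M-ratio) and
#'   pairwise Weir-Cockerham F_ST with bootstrap confidence intervals and
#'   permutation p-values.
NULL

# allele counts per locus for a set of individuals -> list of named integer
# vectors (names = allele sizes as character)
.allele_counts <- function(geno, idx = seq_along(geno$ids)) {
  lapply(seq_along(geno$loci), function(l) {
    al <- c(geno$a1[idx, l], geno$a2[idx, l])
    al <- al[!is.na(al)]
    if (!length(al)) return(integer(0))
    table(al)
  })
}

.he_locus <- function(counts, unbiased = FALSE) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  he <- 1 - sum(p^2)
  if (unbiased && n > 1) he <- he * n / (n - 1)
  he
}

.ho_locus <- function(geno, idx, l) {
  a1 <- geno$a1[idx, l]; a2 <- geno$a2[idx, l]
  ok <- !is.na(a1)
  if (!any(ok)) return(NA_real_)
  mean(a1[ok] != a2[ok])
}

# Weir-Cockerham variance components for a single population: for each
# allele, b = n/(n-1) [p(1-p) - (2n-1)/(4n) h], c = h/2, with h the
# frequency of heterozygotes carrying that allele. F_IS = 1 - sum(c)/sum(b+c)
# over alleles and loci.
.fis_components <- function(geno, idx) {
  b_sum <- 0; c_sum <- 0
  for (l in seq_along(geno$loci)) {
    a1 <- geno$a1[idx, l]; a2 <- geno$a2[idx, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2) next
    a1 <- a1[ok]; a2 <- a2[ok]
    alleles <- unique(c(a1, a2))
    if (length(alleles) < 2) next
    for (al in alleles) {
      p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
      h <- mean((a1 == al) != (a2 == al))
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      b_sum <- b_sum + b
      c_sum <- c_sum + h / 2
    }
  }
  c(b = b_sum, c = c_sum)
}

.fis_value <- function(geno, idx) {
  bc <- .fis_components(geno, idx)
  if (bc["b"] + bc["c"] <= 0) return(NA_real_)
  unname(1 - bc["c"] / (bc["b"] + bc["c"]))
}

# permute alleles among individuals within a population, per locus
.permute_alleles <- function(geno, idx) {
  g <- geno
  for (l in seq_along(g$loci)) {
    ok <- idx[!is.na(g$a1[idx, l])]
    if (length(ok) < 2) next
    pool <- c(g$a1[ok, l], g$a2[ok, l])
    pool <- sample(pool)
    g$a1[ok, l] <- pool[seq_along(ok)]
    g$a2[ok, l] <- pool[length(ok) + seq_along(ok)]
  }
  g
}

#' Per-population microsatellite diversity
#'
#' Computes, for every population of the partition: mean/SD/max number of
#' typed individuals per locus, missing-data proportion, observed and
#' expected heterozygosity (mean +/- SD over loci), the multilocus
#' Weir-Cockerham inbreeding coefficient F_IS (ratio of summed variance
#' components) with a within-population allele-permutation test, and the
#' Garza-Williamson M-ratio.
#'
#' @param geno A [genotype_table()] with allele sizes in repeat units.
#' @param part Partition data frame from [partition()].
#' @param n_perm Number of allele permutations for the F_IS test.
#' @param unbiased_he Apply the small-sample `n/(n-1)` correction to
#'   expected heterozygosity (default `FALSE`, matching the plain
#'   `1 - sum(p^2)` convention).
#' @param seed Optional integer seed for the permutation test.
#' @return Data frame with one row per population.
#' @export
microsat_diversity <- function(geno, part, n_perm = 10000,
                               unbiased_he = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(part$population)
  popv <- .pop_of(geno$ids, part)
  out <- lapply(pops, function(p) {
    idx <- which(!is.na(popv) & popv == p)
    if (length(idx) < 2)
      stop("population ", p, " has fewer than 2 genotyped individuals")
    typed <- colSums(!is.na(geno$a1[idx, , drop = FALSE]))
    counts <- .allele_counts(geno, idx)
    he <- vapply(counts, .he_locus, numeric(1), unbiased = unbiased_he)
    ho <- vapply(seq_along(geno$loci), function(l) .ho_locus(geno, idx, l),
                 numeric(1))
    fis <- .fis_value(geno, idx)
    fis_p <- NA_real_
    if (!is.na(fis) && n_perm > 0) {
      perm <- replicate(n_perm, .fis_value(.permute_alleles(geno, idx), idx))
      fis_p <- (sum(abs(perm) >= abs(fis), na.rm = TRUE) + 1) / (n_perm + 1)
    }
    m <- garza_williamson_m(geno, part)$per_population
    data.frame(population = p,
               n_mean = mean(typed), n_sd = sd(typed), n_max = max(typed),
               na_frac = mean(is.na(geno$a1[idx, , drop = FALSE])),
               ho_mean = mean(ho, na.rm = TRUE), ho_sd = sd(ho, na.rm = TRUE),
               he_mean = mean(he, na.rm = TRUE), he_sd = sd(he, na.rm = TRUE),
               fis = fis, fis_p = fis_p,
               m_gw = m$m_gw[m$population == p],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.rarefied_richness_locus <- function(counts, g) {
  N <- sum(counts)
  if (N < g) return(NA_real_)
  # E[# alleles in a subsample of g copies], hypergeometric absence terms
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, computed per locus from hypergeometric absence
#' probabilities and averaged over loci. Rarefaction operates on gene
#' copies: a target of, say, 26 diploid individuals corresponds to
#' `g = 52`.
#'
#' @param geno A [genotype_table()].
#' @param part Partition data frame.
#' @param g Number of gene copies to rarefy to. Must not exceed the number
#'   of typed copies at any locus in any population.
#' @return List with `per_population` (data frame: mean and SE over loci)
#'   and `per_locus` (matrix loci x populations).
#' @export
allelic_richness <- function(geno, part, g) {
  pops <- levels(part$population)
  popv <- .pop_of(geno$ids, part)
  per_locus <- sapply(pops, function(p) {
    idx <- which(!is.na(popv) & popv == p)
    counts <- .allele_counts(geno, idx)
    N <- vapply(counts, sum, numeric(1))
    short <- which(N < g)
    if (length(short))
      stop("g = ", g, " gene copies exceeds the typed sample at locus ",
           geno$loci[short[1]], " in population ", p, " (N = ",
           N[short[1]], ")")
    vapply(counts, .rarefied_richness_locus, numeric(1), g = g)
  })
  per_locus <- matrix(per_locus, nrow = length(geno$loci),
                      dimnames = list(geno$loci, pops))
  per_pop <- data.frame(
    population = pops,
    ar_mean = colMeans(per_locus),
    ar_se = apply(per_locus, 2, sd) / sqrt(nrow(per_locus)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_population = per_pop, per_locus = per_locus)
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles present in a size-`g` subsample of the focal
#' population and simultaneously absent from independent size-`g`
#' subsamples of every other population (product of hypergeometric absence
#' probabilities), summed over alleles and averaged over loci.
#'
#' @inheritParams allelic_richness
#' @return As [allelic_richness()].
#' @export
private_allelic_richness <- function(geno, part, g) {
  pops <- levels(part$population)
  popv <- .pop_of(geno$ids, part)
  counts_by_pop <- lapply(pops, function(p)
    .allele_counts(geno, which(!is.na(popv) & popv == p)))
  names(counts_by_pop) <- pops
  L <- length(geno$loci)
  per_locus <- matrix(NA_real_, L, length(pops),
                      dimnames = list(geno$loci, pops))
  for (l in seq_len(L)) {
    all_alleles <- sort(unique(unlist(lapply(counts_by_pop, function(cb)
      as.integer(names(cb[[l]]))))))
    N <- vapply(counts_by_pop, function(cb) sum(cb[[l]]), numeric(1))
    if (any(N < g))
      stop("g = ", g, " gene copies exceeds the typed sample at locus ",
           geno$loci[l], " in population ", pops[which(N < g)[1]])
    # n_allele x n_pop matrix of copy counts
    cnt <- sapply(pops, function(p) {
      cb <- counts_by_pop[[p]][[l]]
      out <- setNames(rep(0, length(all_alleles)), all_alleles)
      out[names(cb)] <- as.numeric(cb)
      out
    })
    cnt <- matrix(cnt, nrow = length(all_alleles))
    p_absent <- exp(lchoose(sweep(-cnt, 2, N, "+"), g) -
                      rep(lchoose(N, g), each = nrow(cnt)))
    p_present <- 1 - p_absent
    for (j in seq_along(pops)) {
      others <- p_absent[, -j, drop = FALSE]
      per_locus[l, j] <- sum(p_present[, j] * apply(others, 1, prod))
    }
  }
  per_pop <- data.frame(
    population = pops,
    pa_mean = colMeans(per_locus),
    pa_se = apply(per_locus, 2, sd) / sqrt(nrow(per_locus)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_population = per_pop, per_locus = per_locus)
}

#' Garza-Williamson M-ratio
#'
#' Per locus, `M = k / (r + 1)` where `k` is the number of distinct alleles
#' and `r` the allele-size range in repeat units; bottlenecks depress M
#' because the range shrinks more slowly than the allele count. The
#' population value is the mean over loci; a locus monomorphic within the
#' population has M = 1 and is included by default.
#'
#' @inheritParams allelic_richness
#' @param include_monomorphic Keep within-population monomorphic loci
#'   (M = 1) in the mean (default `TRUE`).
#' @return List with `per_population` (data frame) and `per_locus` matrix.
#' @export
garza_williamson_m <- function(geno, part, include_monomorphic = TRUE) {
  pops <- levels(part$population)
  popv <- .pop_of(geno$ids, part)
  per_locus <- sapply(pops, function(p) {
    idx <- which(!is.na(popv) & popv == p)
    counts <- .allele_counts(geno, idx)
    vapply(counts, function(cnt) {
      if (!length(cnt)) return(NA_real_)
      sizes <- as.integer(names(cnt))
      length(cnt) / (diff(range(sizes)) + 1)
    }, numeric(1))
  })
  n_alleles <- sapply(pops, function(p) {
    idx <- which(!is.na(popv) & popv == p)
    vapply(.allele_counts(geno, idx), length, numeric(1))
  })
  per_locus <- matrix(per_locus, nrow = length(geno$loci),
                      dimnames = list(geno$loci, pops))
  n_alleles <- matrix(n_alleles, nrow = length(geno$loci))
  m <- vapply(seq_along(pops), function(j) {
    v <- per_locus[, j]
    if (!include_monomorphic) v[n_alleles[, j] <= 1] <- NA
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(per_population = data.frame(population = pops, m_gw = unname(m),
                                   stringsAsFactors = FALSE),
       per_locus = per_locus)
}

# Weir-Cockerham (1984) variance components per locus, summed over alleles
# (vectorized over alleles within a locus). Populations with no typed
# individuals at a locus are dropped from that locus; loci with < 2
# populations are skipped. Returns matrix loci x (a,b,c).
.wc_components <- function(a1, a2, pop) {
  L <- ncol(a1)
  popi <- as.integer(pop)
  comp <- matrix(0, L, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (l in seq_len(L)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- which(!is.na(x1))
    if (!length(ok)) next
    x1 <- x1[ok]; x2 <- x2[ok]
    g <- popi[ok]
    ns_all <- tabulate(g, nbins = nlevels(pop))
    use <- which(ns_all >= 1)
    r <- length(use)
    if (r < 2) next
    gi <- match(g, use)
    n_i <- ns_all[use]
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    alleles <- sort(unique(c(x1, x2)))
    A <- length(alleles)
    if (A < 2) next
    ai1 <- match(x1, alleles); ai2 <- match(x2, alleles)
    cnt <- matrix(tabulate((gi - 1L) * A + ai1, A * r) +
                    tabulate((gi - 1L) * A + ai2, A * r), A, r)
    p_i <- sweep(cnt, 2, 2 * n_i, "/")
    het <- which(x1 != x2)
    h_cnt <- matrix(tabulate((gi[het] - 1L) * A + ai1[het], A * r) +
                      tabulate((gi[het] - 1L) * A + ai2[het], A * r), A, r)
    h_i <- sweep(h_cnt, 2, n_i, "/")
    pbar <- as.vector(p_i %*% n_i) / (r * nbar)
    s2 <- as.vector((p_i - pbar)^2 %*% n_i) / ((r - 1) * nbar)
    hbar <- as.vector(h_i %*% n_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    comp[l, ] <- c(sum(a), sum(b), sum(hbar) / 2)
  }
  comp
}

#' Multilocus Weir-Cockerham F-statistics
#'
#' Variance-component estimators of theta (F_ST), F_IS and F_IT, multilocus
#' values as ratios of components summed over alleles and loci.
#'
#' @param geno A [genotype_table()].
#' @param part Partition data frame.
#' @return List with `theta`, `fis`, `fit` and the per-locus component
#'   matrix `components`.
#' @export
wc_fstats <- function(geno, part) {
  pop <- .pop_of(geno$ids, part)
  keep <- !is.na(pop)
  comp <- .wc_components(geno$a1[keep, , drop = FALSE],
                         geno$a2[keep, , drop = FALSE], droplevels(pop[keep]))
  s <- colSums(comp)
  list(theta = unname(s["a"] / sum(s)),
       fis = unname(1 - s["c"] / (s["b"] + s["c"])),
       fit = unname(1 - s["c"] / sum(s)),
       components = comp)
}

.theta_from_comp <- function(comp, loci = seq_len(nrow(comp))) {
  s <- colSums(comp[loci, , drop = FALSE])
  tot <- sum(s)
  if (tot == 0) return(NA_real_)
  unname(s["a"] / tot)
}

#' Pairwise Weir-Cockerham F_ST for microsatellites
#'
#' For every population pair: the multilocus theta, a 95% confidence
#' interval from bootstrap resampling of loci, and a p-value from permuting
#' individuals between the two populations.
#'
#' @param geno A [genotype_table()].
#' @param part Partition data frame.
#' @param n_boot Bootstrap resamples over loci for the CI (`NA` CI when
#'   fewer than 2 informative loci).
#' @param n_perm Permutations of individuals for the p-value.
#' @param seed Optional integer seed.
#' @return Data frame: `pop1`, `pop2`, `fst`, `ci_low`, `ci_high`,
#'   `p_value`, `marker = "microsatellite"`.
#' @export
pairwise_fst_microsat <- function(geno, part, n_boot = 10000,
                                  n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(part$population)
  popv <- .pop_of(geno$ids, part)
  pairs <- combn(pops, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    idx <- which(!is.na(popv) & popv %in% c(p1, p2))
    pop2 <- factor(as.character(popv[idx]), levels = c(p1, p2))
    a1 <- geno$a1[idx, , drop = FALSE]; a2 <- geno$a2[idx, , drop = FALSE]
    comp <- .wc_components(a1, a2, pop2)
    theta <- .theta_from_comp(comp)
    informative <- which(rowSums(abs(comp)) > 0)
    ci <- c(NA_real_, NA_real_)
    if (length(informative) >= 2 && n_boot > 0) {
      bt <- replicate(n_boot, .theta_from_comp(
        comp, sample(nrow(comp), replace = TRUE)))
      ci <- unname(quantile(bt, c(0.025, 0.975), na.rm = TRUE))
    }
    pv <- NA_real_
    if (n_perm > 0 && !is.na(theta)) {
      perm <- replicate(n_perm, {
        .theta_from_comp(.wc_components(a1, a2, sample(pop2)))
      })
      pv <- (sum(perm >= theta, na.rm = TRUE) + 1) / (n_perm + 1)
    }
    data.frame(pop1 = p1, pop2 = p2, fst = theta, ci_low = ci[1],
               ci_high = ci[2], p_value = pv, marker = "microsatellite",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
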