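#' @name summary-stats
#' @title Summary-statistic vector for ABC
#' @description The fixed-order statistic vector describing a two-marker
#'   dataset: per population the mean allele count, mean expected
#'   heterozygosity, mean allele-size variance and M-ratio for the
#'   microsatellites, and S, haplotype diversity, nucleotide diversity and
#'   Tajima's D (imputed as 0 with a companion indicator when degenerate,
#'   so mtDNA monomorphism is itself informative) for the sequences; per
#'   population pair the Weir-Cockerham F_ST, the shared-allele distance,
#'   the (delta mu)^2 distance and the Hudson mtDNA F_ST. Non-finite values
#'   are imputed as 0.
NULL

.base_count_matrix <- function(tips, idx) {
  # 4 x S counts of bases (0..3) among rows idx
  S <- ncol(tips)
  if (S == 0) return(matrix(0, 4, 0))
  vapply(seq_len(S), function(s) tabulate(tips[idx, s] + 1L, 4L),
         numeric(4))
}

.mt_pop_stats <- function(tips, idx, L) {
  n <- length(idx)
  cnt <- .base_count_matrix(tips, idx)
  seg <- colSums(cnt > 0) > 1
  S <- sum(seg)
  pi_tot <- if (n > 1) sum((n^2 - colSums(cnt^2)) / (n * (n - 1))) else 0
  hap <- if (ncol(tips)) table(apply(tips[idx, , drop = FALSE], 1, paste,
                                     collapse = ",")) else
    setNames(n, "x")
  hd <- if (n > 1) n / (n - 1) * (1 - sum((hap / n)^2)) else 0
  td <- .tajima_d(n, S, pi_tot)
  c(mtS = S, mtHd = hd, mtPi = pi_tot / L,
    mtD = td$d, mtDdeg = as.numeric(td$degenerate))
}

.mt_pair_fst <- function(tips, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  c1 <- .base_count_matrix(tips, idx1)
  c2 <- .base_count_matrix(tips, idx2)
  w1 <- if (n1 > 1) sum((n1^2 - colSums(c1^2)) / (n1 * (n1 - 1))) else NA
  w2 <- if (n2 > 1) sum((n2^2 - colSums(c2^2)) / (n2 * (n2 - 1))) else NA
  hb <- sum(n1 * n2 - colSums(c1 * c2)) / (n1 * n2)
  if (!is.finite(hb) || hb == 0) return(NA_real_)
  1 - mean(c(w1, w2)) / hb
}

#' Names of the summary-statistic vector for a set of populations
#' @param pops Character vector of population names.
#' @return Character vector of statistic names in fixed order.
#' @export
ss_names <- function(pops) {
  per_pop <- c("k", "he", "vsize", "mgw", "mtS", "mtHd", "mtPi", "mtD",
               "mtDdeg")
  pair <- combn(pops, 2)
  c(as.vector(t(outer(pops, per_pop, paste, sep = "_"))),
    as.vector(vapply(seq_len(ncol(pair)), function(j)
      paste(pair[1, j], pair[2, j], c("fst", "das", "dmu2", "mtfst"),
            sep = "_"), character(4))))
}

#' Compute the summary-statistic vector
#'
#' @param a1,a2 Integer allele matrices (individuals x loci); `NA` for
#'   missing genotypes.
#' @param pop Factor of population labels, one per individual.
#' @param mt_tips Integer matrix (sequences x variable sites, bases coded
#'   0..3); may have zero columns.
#' @param mt_pop Factor of population labels, one per sequence.
#' @param mt_length Total number of (usable) sites for per-site scaling.
#' @return Named numeric vector in the order of [ss_names()].
#' @export
compute_ss <- function(a1, a2, pop, mt_tips, mt_pop, mt_length) {
  pops <- levels(pop)
  L <- ncol(a1)
  out <- numeric(0)
  freq_by_pop <- vector("list", length(pops))
  names(freq_by_pop) <- pops
  for (p in pops) {
    idx <- which(pop == p)
    k <- he <- vs <- mgw <- numeric(L)
    freqs <- vector("list", L)
    for (l in seq_len(L)) {
      al <- c(a1[idx, l], a2[idx, l])
      al <- al[!is.na(al)]
      if (!length(al)) {
        k[l] <- he[l] <- vs[l] <- NA; mgw[l] <- NA
        freqs[[l]] <- numeric(0)
        next
      }
      ua <- sort.int(unique(al))
      pr <- tabulate(match(al, ua), length(ua)) / length(al)
      k[l] <- length(ua)
      he[l] <- 1 - sum(pr^2)
      vs[l] <- if (length(al) > 1) var(al) else 0
      mgw[l] <- length(ua) / (ua[length(ua)] - ua[1] + 1)
      freqs[[l]] <- setNames(pr, ua)
    }
    freq_by_pop[[p]] <- freqs
    midx <- which(mt_pop == p)
    mts <- .mt_pop_stats(mt_tips, midx, mt_length)
    v <- c(k = mean(k, na.rm = TRUE), he = mean(he, na.rm = TRUE),
           vsize = mean(vs, na.rm = TRUE), mgw = mean(mgw, na.rm = TRUE),
           mts)
    names(v) <- paste(p, c("k", "he", "vsize", "mgw", "mtS", "mtHd",
                           "mtPi", "mtD", "mtDdeg"), sep = "_")
    out <- c(out, v)
  }
  pair <- combn(pops, 2)
  for (j in seq_len(ncol(pair))) {
    p1 <- pair[1, j]; p2 <- pair[2, j]
    sel <- pop %in% c(p1, p2)
    comp <- .wc_components(a1[sel, , drop = FALSE], a2[sel, , drop = FALSE],
                           factor(as.character(pop[sel]),
                                  levels = c(p1, p2)))
    theta <- .theta_from_comp(comp)
    das <- dmu2 <- numeric(L)
    for (l in seq_len(L)) {
      f1 <- freq_by_pop[[p1]][[l]]; f2 <- freq_by_pop[[p2]][[l]]
      alleles <- union(names(f1), names(f2))
      g1 <- setNames(rep(0, length(alleles)), alleles)
      g2 <- g1
      g1[names(f1)] <- f1; g2[names(f2)] <- f2
      das[l] <- 1 - sum(pmin(g1, g2))
      m1 <- sum(as.numeric(alleles) * g1)
      m2 <- sum(as.numeric(alleles) * g2)
      dmu2[l] <- (m1 - m2)^2
    }
    mfst <- .mt_pair_fst(mt_tips, which(mt_pop == p1), which(mt_pop == p2))
    v <- c(theta, mean(das, na.rm = TRUE), mean(dmu2, na.rm = TRUE), mfst)
    names(v) <- paste(p1, p2, c("fst", "das", "dmu2", "mtfst"), sep = "_")
    out <- c(out, v)
  }
  out[!is.finite(out)] <- 0
  out
}

.ss_from_raw <- function(raw, design) {
  if (is.null(raw$mt)) {
    tips <- matrix(0L, 0, 0)
    mt_pop <- factor(character(0), levels = design$pops)
  } else {
    tips <- raw$mt$tips
    mt_pop <- raw$mt$pop
  }
  compute_ss(raw$a1, raw$a2, raw$pop, tips, mt_pop, design$mt_length)
}

#' Summary-statistic vector of an observed dataset
#'
#' Maps observed containers onto the same statistic vector the simulator
#' produces, restricted to the populations used in the ABC analysis.
#'
#' @param geno A [genotype_table()].
#' @param mt A [haplotype_alignment()] (or `NULL`).
#' @param part Partition data frame.
#' @param pops Populations to include, in order (default: all partition
#'   levels).
#' @return Named numeric vector in the order of [ss_names()].
#' @export
observed_ss <- function(geno, mt, part, pops = levels(part$population)) {
  popv <- .pop_of(geno$ids, part)
  keep <- !is.na(popv) & popv %in% pops
  pop <- factor(as.character(popv[keep]), levels = pops)
  if (!is.null(mt)) {
    mpop <- .pop_of(mt$ids, part)
    mkeep <- !is.na(mpop) & mpop %in% pops
    m <- .site_matrix(mt, which(mkeep))
    tips <- matrix(match(m, .BASES) - 1L, nrow = nrow(m))
    var_cols <- which(apply(tips, 2, function(cc) length(unique(cc)) > 1))
    L_use <- ncol(tips)
    tips <- tips[, var_cols, drop = FALSE]
    mt_pop <- factor(as.character(mpop[mkeep]), levels = pops)
  } else {
    tips <- matrix(0L, sum(keep), 0)
    L_use <- 1
    mt_pop <- factor(character(0), levels = pops)
  }
  compute_ss(geno$a1[keep, , drop = FALSE], geno$a2[keep, , drop = FALSE],
             pop, tips, mt_pop, L_use)
}
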