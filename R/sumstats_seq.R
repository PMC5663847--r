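#' @name sequence-diversity
#' @title Control-region sequence diversity and differentiation
#' @description Segregating sites, singleton/shared polymorphism counts,
#'   haplotype and nucleotide diversity, Watterson's theta, Tajima's D with
#'   a coalescent significance test, Hudson's F_ST from mean pairwise
#'   differences, and the Snn nearest-neighbour permutation test.
NULL

# integer site matrix restricted to usable sites, rows = selected sequences
.site_matrix <- function(mt, idx = seq_along(mt$ids)) {
  m <- .seq_matrix(mt$seq[idx])
  m[, usable_sites(mt), drop = FALSE]
}

.harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

# per-site state counts -> S, singletons, mean pairwise differences
.seq_core <- function(m) {
  n <- nrow(m)
  if (ncol(m) == 0) return(list(S = 0, singletons = 0, pi_total = 0))
  stats_site <- apply(m, 2, function(col) {
    tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")), 4)
    nst <- sum(tab > 0)
    c(seg = as.numeric(nst > 1),
      singleton = as.numeric(nst > 1 && (n - max(tab)) == 1),
      pairdiff = (n^2 - sum(tab^2)) / (n * (n - 1)))
  })
  list(S = sum(stats_site["seg", ]),
       singletons = sum(stats_site["singleton", ]),
       pi_total = sum(stats_site["pairdiff", ]))  # mean pairwise differences
}

.tajima_d <- function(n, S, pi_total) {
  if (S == 0 || n < 4) return(list(d = 0, degenerate = TRUE))
  a1 <- .harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  list(d = (pi_total - S / a1) / sqrt(v), degenerate = FALSE)
}

#' Sequence diversity per population
#'
#' For each population (and the pooled total): number of sequences `n`,
#' segregating sites `S` split into singletons and shared polymorphisms,
#' haplotype count and diversity `Hd = n/(n-1) (1 - sum p_h^2)`, nucleotide
#' diversity `pi` (mean pairwise differences per usable site), Watterson's
#' `theta_W = S / (a_{n-1} L)` and Tajima's D (reported as 0 with a
#' degenerate flag for monomorphic samples). Excluded (non-ACGT) sites are
#' dropped listwise.
#'
#' @param mt A [haplotype_alignment()].
#' @param part Optional partition data frame; rows for unlabelled sequences
#'   are ignored, and a `Total` row over all labelled sequences is added.
#' @return Data frame, one row per population plus `Total`.
#' @export
sequence_diversity <- function(mt, part = NULL) {
  groups <- if (is.null(part)) {
    list(Total = seq_along(mt$ids))
  } else {
    popv <- .pop_of(mt$ids, part)
    g <- lapply(levels(part$population), function(p)
      which(!is.na(popv) & popv == p))
    names(g) <- levels(part$population)
    c(g, list(Total = which(!is.na(popv))))
  }
  out <- lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    n <- length(idx)
    if (n < 2)
      return(data.frame(population = nm, n = n, S = NA, singletons = NA,
                        shared = NA, n_hap = NA, hd = NA, pi = NA,
                        theta_w = NA, tajima_d = NA, d_degenerate = NA))
    m <- .site_matrix(mt, idx)
    L <- ncol(m)
    core <- .seq_core(m)
    hap <- table(apply(m, 1, paste, collapse = ""))
    hd <- n / (n - 1) * (1 - sum((hap / n)^2))
    td <- .tajima_d(n, core$S, core$pi_total)
    data.frame(population = nm, n = n, S = core$S,
               singletons = core$singletons,
               shared = core$S - core$singletons,
               n_hap = length(hap), hd = hd,
               pi = core$pi_total / L,
               theta_w = core$S / (.harmonic(n - 1) * L),
               tajima_d = td$d, d_degenerate = td$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# one standard-coalescent replicate conditioned on theta (per locus):
# returns (S, pi_total) using mutation placement proportional to branch
# length; w tracks tips subtended by each lineage.
.sim_d_replicate <- function(n, theta) {
  w <- rep(1L, n)
  int_len <- numeric(n - 1)
  weights_list <- vector("list", n - 1)
  for (k in n:2) {
    i <- n - k + 1
    int_len[i] <- rexp(1, rate = k * (k - 1) / 2)
    weights_list[[i]] <- w
    pair <- sample.int(k, 2)
    w[pair[1]] <- w[pair[1]] + w[pair[2]]
    w <- w[-pair[2]]
  }
  expo <- int_len * (n:2)  # total branch exposure per interval
  total <- sum(expo)
  S <- rpois(1, theta / 2 * total)
  if (S == 0) return(c(S = 0, pi = 0))
  per_int <- as.vector(rmultinom(1, S, expo / total))
  pi_tot <- 0
  npairs <- n * (n - 1) / 2
  for (i in which(per_int > 0)) {
    wl <- weights_list[[i]]
    picked <- sample.int(length(wl), per_int[i], replace = TRUE)
    pi_tot <- pi_tot + sum(wl[picked] * (n - wl[picked])) / npairs
  }
  c(S = S, pi = pi_tot)
}

#' Tajima's D with a coalescent significance test
#'
#' Computes Tajima's D for a set of sequences and evaluates its two-tailed
#' significance against constant-size neutral coalescent simulations
#' conditioned on the sample size and the observed Watterson estimate
#' `theta_W` (per locus).
#'
#' @param mt A [haplotype_alignment()] (or subset of one).
#' @param n_sims Number of coalescent replicates (default 10000).
#' @param seed Optional integer seed.
#' @return List with `d`, `p_value`, `degenerate` and the simulated null
#'   distribution `null_d`.
#' @export
tajima_d_test <- function(mt, n_sims = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(mt$ids)
  m <- .site_matrix(mt)
  core <- .seq_core(m)
  td <- .tajima_d(n, core$S, core$pi_total)
  if (td$degenerate)
    return(list(d = 0, p_value = NA_real_, degenerate = TRUE,
                null_d = numeric(0)))
  theta <- core$S / .harmonic(n - 1)
  null_d <- vapply(seq_len(n_sims), function(i) {
    r <- .sim_d_replicate(n, theta)
    .tajima_d(n, r["S"], r["pi"])$d
  }, numeric(1))
  lo <- mean(null_d <= td$d)
  hi <- mean(null_d >= td$d)
  list(d = td$d, p_value = min(1, 2 * min(lo, hi)), degenerate = FALSE,
       null_d = null_d)
}

.hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

.hudson_fst <- function(d, grp) {
  g <- unique(grp)
  within <- vapply(g, function(p) {
    i <- which(grp == p)
    if (length(i) < 2) return(NA_real_)
    mean(d[i, i][upper.tri(d[i, i])])
  }, numeric(1))
  i1 <- which(grp == g[1]); i2 <- which(grp == g[2])
  hb <- mean(d[i1, i2, drop = FALSE])
  hw <- mean(within)  # equal population weights
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

.snn_stat <- function(d, grp) {
  n <- nrow(d)
  x <- vapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    nn <- which(dd == min(dd))
    others <- grp[-i]
    mean(others[nn] == grp[i])  # ties split equally
  }, numeric(1))
  mean(x)
}

#' Hudson's nearest-neighbour test (Snn)
#'
#' Snn is the mean, over sequences, of the fraction of each sequence's
#' nearest neighbours (Hamming distance over usable sites, ties split
#' equally) that belong to its own population. Significance comes from
#' permuting population labels.
#'
#' @param mt A [haplotype_alignment()].
#' @param part Partition data frame restricted to two populations (larger
#'   partitions are accepted; the test then uses all labelled populations).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `snn`, `p_value`, `n_permutations`.
#' @export
snn_test <- function(mt, part, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  popv <- .pop_of(mt$ids, part)
  idx <- which(!is.na(popv))
  grp <- as.character(popv[idx])
  m <- .site_matrix(mt, idx)
  d <- .hamming_matrix(m)
  obs <- .snn_stat(d, grp)
  perm <- replicate(n_perm, .snn_stat(d, sample(grp)))
  list(snn = obs, p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
       n_permutations = n_perm)
}

#' Pairwise mtDNA F_ST (Hudson) with Snn significance
#'
#' `F_ST = 1 - H_w / H_b` where `H_w` is the mean of the two
#' within-population mean pairwise differences (equal population weights)
#' and `H_b` the mean between-population pairwise difference. Populations
#' with a single sequence are excluded with a warning. Significance comes
#' from the [snn_test()] permutation procedure on each pair.
#'
#' @param mt A [haplotype_alignment()].
#' @param part Partition data frame.
#' @param n_perm Snn permutations per pair.
#' @param seed Optional integer seed.
#' @return Data frame: `pop1`, `pop2`, `fst`, `snn`, `p_value`,
#'   `marker = "mtDNA"`.
#' @export
pairwise_fst_mtdna <- function(mt, part, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  popv <- .pop_of(mt$ids, part)
  sizes <- table(popv[!is.na(popv)])
  pops <- names(sizes)[sizes >= 2]
  drop <- setdiff(levels(part$population), pops)
  if (length(drop))
    warning("excluding populations with < 2 sequences: ",
            paste(drop, collapse = ", "))
  pairs <- combn(pops, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    idx <- which(!is.na(popv) & popv %in% c(p1, p2))
    grp <- as.character(popv[idx])
    m <- .site_matrix(mt, idx)
    d <- .hamming_matrix(m)
    fst <- .hudson_fst(d, grp)
    obs <- .snn_stat(d, grp)
    perm <- replicate(n_perm, .snn_stat(d, sample(grp)))
    data.frame(pop1 = p1, pop2 = p2, fst = fst, snn = obs,
               p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
               marker = "mtDNA", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
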