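# independent single-population variance-component oracle, written as a
# direct transcription of the per-allele formulas with explicit loops
fis_oracle <- function(a1, a2) {
  b_sum <- 0; c_sum <- 0
  for (l in seq_len(ncol(a1))) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- !is.na(x1)
    n <- sum(ok)
    alleles <- unique(c(x1[ok], x2[ok]))
    if (length(alleles) < 2 || n < 2) next
    for (al in alleles) {
      p <- 0; h <- 0
      for (i in which(ok)) {
        p <- p + (x1[i] == al) + (x2[i] == al)
        h <- h + as.numeric(xor(x1[i] == al, x2[i] == al))
      }
      p <- p / (2 * n); h <- h / n
      b_sum <- b_sum + n / (n - 1) *
        (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      c_sum <- c_sum + h / 2
    }
  }
  unname(1 - c_sum / (b_sum + c_sum))
}

test_that("expected heterozygosity matches the closed form", {
  # one locus with two alleles at 0.5/0.5
  g <- genotype_table(paste0("i", 1:4), "L1",
                      matrix(c(10L, 10L, 11L, 11L)),
                      matrix(c(10L, 11L, 10L, 11L)))
  p <- partition(g$ids, rep("A", 4))
  d <- microsat_diversity(g, p, n_perm = 0)
  expect_equal(d$he_mean, 0.5)
  expect_equal(d$ho_mean, 0.5)
})

test_that("per-population F_IS equals an independent variance-component
          evaluation", {
  set.seed(21)
  for (i in 1:4) {
    g <- random_genotype_table(n = 6, L = 2, missing = 0.1)
    p <- partition(g$ids, rep("A", 6))
    d <- microsat_diversity(g, p, n_perm = 0)
    expect_equal(d$fis, fis_oracle(g$a1, g$a2), tolerance = 1e-12)
  }
})

test_that("F_IS permutation test is two-sided and near-null on HW data", {
  set.seed(22)
  # draw genotypes under Hardy-Weinberg: alleles iid from a frequency pool
  a1 <- matrix(sample(10:13, 40 * 5, TRUE), 40, 5)
  a2 <- matrix(sample(10:13, 40 * 5, TRUE), 40, 5)
  g <- genotype_table(sprintf("i%02d", 1:40), paste0("L", 1:5), a1, a2)
  p <- partition(g$ids, rep("A", 40))
  d <- microsat_diversity(g, p, n_perm = 300, seed = 5)
  expect_gt(d$fis_p, 0.05)
})

test_that("rarefied allelic richness matches exhaustive enumeration", {
  # counts (3,1), N = 4, g = 2: enumerate all C(4,2) subsamples
  g <- genotype_table(c("a", "b"), "L1", matrix(c(10L, 10L)),
                      matrix(c(10L, 12L)))
  p <- partition(g$ids, c("A", "A"))
  copies <- c(10, 10, 10, 12)
  combs <- combn(4, 2)
  expected <- mean(apply(combs, 2, function(j)
    length(unique(copies[j]))))
  ar <- allelic_richness(g, p, g = 2)
  expect_equal(ar$per_population$ar_mean, expected)
  expect_equal(expected, 1.5)
  # g equal to the full sample reproduces the raw allele count exactly
  ar_full <- allelic_richness(g, p, g = 4)
  expect_equal(ar_full$per_population$ar_mean, 2)
  # g beyond the available copies names the offending locus
  expect_error(allelic_richness(g, p, g = 6), "L1")
})

test_that("private allelic richness matches brute-force subsampling", {
  # trivial cases: same fixed allele -> 0; different fixed alleles -> 1
  g1 <- genotype_table(paste0("i", 1:4), "L1", matrix(rep(10L, 4)),
                       matrix(rep(10L, 4)))
  p2 <- partition(g1$ids, c("A", "A", "B", "B"))
  expect_equal(private_allelic_richness(g1, p2, 2)$per_population$pa_mean,
               c(0, 0))
  g2 <- genotype_table(paste0("i", 1:4), "L1",
                       matrix(c(10L, 10L, 14L, 14L)),
                       matrix(c(10L, 10L, 14L, 14L)))
  expect_equal(private_allelic_richness(g2, p2, 2)$per_population$pa_mean,
               c(1, 1))
  # 3-population toy against exhaustive enumeration of subsample triples
  set.seed(23)
  a1 <- matrix(sample(10:12, 9, TRUE), 9, 1)
  a2 <- matrix(sample(10:12, 9, TRUE), 9, 1)
  g3 <- genotype_table(paste0("i", 1:9), "L1", a1, a2)
  p3 <- partition(g3$ids, rep(c("A", "B", "C"), each = 3))
  gg <- 2
  pools <- lapply(split(seq_len(9), rep(1:3, each = 3)), function(idx)
    c(a1[idx, 1], a2[idx, 1]))
  subsets <- lapply(pools, function(pool) combn(length(pool), gg))
  brute <- sapply(1:3, function(focal) {
    others <- setdiff(1:3, focal)
    total <- 0; count <- 0
    sf <- subsets[[focal]]; s1 <- subsets[[others[1]]]
    s2 <- subsets[[others[2]]]
    for (i in seq_len(ncol(sf))) for (j in seq_len(ncol(s1)))
      for (k in seq_len(ncol(s2))) {
        af <- pools[[focal]][sf[, i]]
        ao <- c(pools[[others[1]]][s1[, j]], pools[[others[2]]][s2[, k]])
        total <- total + length(setdiff(unique(af), ao))
        count <- count + 1
      }
    total / count
  })
  pa <- private_allelic_richness(g3, p3, gg)$per_population$pa_mean
  expect_equal(pa, brute, tolerance = 1e-10)
})

test_that("the M-ratio follows its closed form and is translation
          invariant", {
  g <- genotype_table(paste0("i", 1:3), c("L1", "L2"),
                      matrix(c(10L, 11L, 12L, 50L, 52L, 54L), 3, 2),
                      matrix(c(10L, 11L, 12L, 50L, 52L, 54L), 3, 2))
  p <- partition(g$ids, rep("A", 3))
  m <- garza_williamson_m(g, p)
  expect_equal(unname(m$per_locus[, 1]), c(1, 0.6))
  # adding a constant to all allele sizes leaves M unchanged
  g2 <- g; g2$a1 <- g$a1 + 7L; g2$a2 <- g$a2 + 7L
  expect_equal(garza_williamson_m(g2, p)$per_population$m_gw,
               m$per_population$m_gw)
  # a monomorphic locus contributes M = 1 by default and can be excluded
  g3 <- genotype_table(paste0("i", 1:3), c("L1", "L2"),
                       matrix(c(10L, 10L, 10L, 50L, 52L, 54L), 3, 2),
                       matrix(c(10L, 10L, 10L, 50L, 52L, 54L), 3, 2))
  expect_equal(garza_williamson_m(g3, p)$per_population$m_gw,
               mean(c(1, 0.6)))
  expect_equal(garza_williamson_m(g3, p,
               include_monomorphic = FALSE)$per_population$m_gw, 0.6)
})

test_that("pairwise Weir-Cockerham theta hits the fixation and panmixia
          limits", {
  # two populations fixed for different alleles at all loci -> theta ~ 1
  n <- 10
  a1 <- rbind(matrix(10L, n, 3), matrix(15L, n, 3))
  g <- genotype_table(sprintf("i%02d", 1:(2 * n)), paste0("L", 1:3),
                      a1, a1)
  p <- partition(g$ids, rep(c("A", "B"), each = n))
  fst <- pairwise_fst_microsat(g, p, n_boot = 0, n_perm = 100, seed = 1)
  expect_gt(fst$fst, 0.95)
  expect_lt(fst$p_value, 0.05)
  # two samples from one panmictic pool: mean theta ~ 0 over replicates
  set.seed(24)
  thetas <- replicate(200, {
    a1 <- matrix(sample(10:14, 2 * 30 * 4, TRUE), 60, 4)
    a2 <- matrix(sample(10:14, 2 * 30 * 4, TRUE), 60, 4)
    gg <- genotype_table(sprintf("i%02d", 1:60), paste0("L", 1:4), a1, a2)
    pp <- partition(gg$ids, rep(c("A", "B"), each = 30))
    wc_fstats(gg, pp)$theta
  })
  expect_lt(abs(mean(thetas)), 0.005)
})

test_that("theta and the bootstrap CI behave on structured data", {
  set.seed(25)
  # moderately diverged allele-frequency regimes
  a1 <- rbind(matrix(sample(10:12, 60, TRUE, prob = c(.7, .2, .1)), 20, 3),
              matrix(sample(10:12, 60, TRUE, prob = c(.1, .2, .7)), 20, 3))
  a2 <- rbind(matrix(sample(10:12, 60, TRUE, prob = c(.7, .2, .1)), 20, 3),
              matrix(sample(10:12, 60, TRUE, prob = c(.1, .2, .7)), 20, 3))
  g <- genotype_table(sprintf("i%02d", 1:40), paste0("L", 1:3), a1, a2)
  p <- partition(g$ids, rep(c("A", "B"), each = 20))
  fst <- pairwise_fst_microsat(g, p, n_boot = 300, n_perm = 300, seed = 2)
  expect_true(fst$ci_low <= fst$fst && fst$fst <= fst$ci_high)
  expect_lt(fst$p_value, 0.05)
  expect_gt(fst$fst, 0.1)
})
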