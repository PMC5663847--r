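# independent Tajima's D oracle: direct transcription of the published
# variance formula, with pi from explicit pairwise comparisons
tajima_oracle <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  S <- sum(apply(m, 2, function(cc) length(unique(cc)) > 1))
  pi_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pi_tot <- pi_tot + sum(m[i, ] != m[j, ])
  pi_tot <- pi_tot / choose(n, 2)
  if (S == 0) return(0)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_tot - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

random_alignment <- function(n = 8, L = 30) {
  haplotype_alignment(sprintf("s%02d", 1:n),
                      vapply(1:n, function(i)
                        paste(sample(c("A", "C", "G", "T"), L, TRUE,
                                     prob = c(.55, .15, .15, .15)),
                              collapse = ""), character(1)))
}

test_that("sequence diversity matches a hand-counted toy alignment", {
  mt <- haplotype_alignment(paste0("s", 1:4),
                            c("AAAAAAAAAA", "AAAAAAAAAT",
                              "AAAAAAAATT", "AAAAAAATTT"))
  d <- sequence_diversity(mt)
  expect_equal(d$S, 3)
  expect_equal(d$singletons, 2)
  expect_equal(d$shared, 1)
  expect_equal(d$n_hap, 4)
  expect_equal(d$hd, 1)
  expect_equal(d$pi, (0.5 + 4 / 6 + 0.5) / 10)
  expect_equal(d$theta_w, 3 / (sum(1 / (1:3)) * 10))
})

test_that("monomorphic samples give the degenerate pattern the study's
          fixed-haplotype cluster shows", {
  mt <- haplotype_alignment(paste0("s", 1:5), rep("ACGTACGTAC", 5))
  d <- sequence_diversity(mt)
  expect_equal(d$S, 0)
  expect_equal(d$n_hap, 1)
  expect_equal(d$hd, 0)
  expect_equal(d$pi, 0)
  expect_equal(d$theta_w, 0)
  expect_equal(d$tajima_d, 0)
  expect_true(d$d_degenerate)
  td <- tajima_d_test(mt, n_sims = 100)
  expect_true(td$degenerate)
})

test_that("Tajima's D equals the independent formula oracle", {
  set.seed(31)
  for (i in 1:6) {
    mt <- random_alignment(n = sample(4:10, 1), L = 25)
    d <- sequence_diversity(mt)
    expect_equal(d$tajima_d, tajima_oracle(mt$seq), tolerance = 1e-10)
  }
})

test_that("segregating sites split exactly into singletons and shared
          polymorphisms", {
  set.seed(32)
  for (i in 1:10) {
    mt <- random_alignment(n = sample(4:12, 1), L = 40)
    d <- sequence_diversity(mt)
    expect_equal(d$S, d$singletons + d$shared)
  }
})

test_that("the coalescent D test is near-null for neutral constant-size
          data", {
  set.seed(33)
  dem <- constant_demography(300)
  model <- mutation_model(mu_mt = 5e-5, kappa = 5)
  gen <- sample_genealogy(dem, c(pop1 = 12L), "mtDNA")
  res <- mutate_sequence(gen, model, 200)
  seqs <- apply(res$tips, 1, function(r)
    paste(c("A", "C", "G", "T")[r + 1], collapse = ""))
  mt <- haplotype_alignment(sprintf("s%02d", 1:12), unname(seqs))
  td <- tajima_d_test(mt, n_sims = 800, seed = 4)
  expect_gt(td$p_value, 0.01)
})

test_that("Hudson F_ST hits its limits and ignores haplotype labels", {
  # fixed different haplotypes -> F_ST = 1
  mt <- haplotype_alignment(paste0("s", 1:6),
                            c(rep("AAAA", 3), rep("TTTT", 3)))
  p <- partition(mt$ids, rep(c("A", "B"), each = 3))
  fst <- pairwise_fst_mtdna(mt, p, n_perm = 100, seed = 1)
  expect_equal(fst$fst, 1)
  # two samples from one haplotype pool -> F_ST ~ 0 (slightly negative in
  # expectation because within-sample diversity is computed over n(n-1)/2
  # pairs)
  set.seed(35)
  fst0 <- replicate(30, {
    mt2 <- random_alignment(n = 24, L = 20)
    p2 <- partition(mt2$ids, sample(rep(c("A", "B"), each = 12)))
    pairwise_fst_mtdna(mt2, p2, n_perm = 0, seed = 1)$fst
  })
  expect_lt(abs(mean(fst0)), 0.05)
  # relabelling haplotypes (A<->G everywhere) changes nothing
  mt3 <- haplotype_alignment(mt$ids, chartr("AT", "GC", mt$seq))
  fst3 <- pairwise_fst_mtdna(mt3, p, n_perm = 100, seed = 1)
  expect_equal(fst3$fst, fst$fst)
})

test_that("Snn matches brute-force fractional tie counting", {
  # 6 sequences engineered with a tie: s1 equidistant from own-pop s2 and
  # other-pop s4
  seqs <- c("AAAA", "AAAT", "AATT", "AAAG", "GGGG", "GGGT")
  mt <- haplotype_alignment(paste0("s", 1:6), seqs)
  p <- partition(mt$ids, rep(c("A", "B"), each = 3))
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])  # Hamming, by hand
  # brute-force x_i with ties split equally
  grp <- rep(c("A", "B"), each = 3)
  x <- sapply(1:6, function(i) {
    dd <- d[i, -i]; nn <- which(dd == min(dd))
    mean(grp[-i][nn] == grp[i])
  })
  res <- snn_test(mt, p, n_perm = 200, seed = 2)
  expect_equal(res$snn, mean(x))
  # disjoint haplotype sets -> Snn = 1; with 8 + 8 sequences only the two
  # label assignments matching the split reproduce Snn = 1, so p is
  # minimal
  suffixes <- c("AA", "AT", "AG", "AC", "TA", "TT", "TG", "TC")
  seqs_a <- paste0("AAAAAAA", suffixes)
  seqs_b <- paste0("GGGGGGG", suffixes)
  mtd <- haplotype_alignment(paste0("s", 1:16), c(seqs_a, seqs_b))
  pd <- partition(mtd$ids, rep(c("A", "B"), each = 8))
  resd <- snn_test(mtd, pd, n_perm = 200, seed = 3)
  expect_equal(resd$snn, 1)
  expect_lte(resd$p_value, 2 / 200 + 1 / 201)
})

test_that("Snn permutation p-values are calibrated under random labels", {
  set.seed(34)
  ps <- replicate(60, {
    mt <- random_alignment(n = 10, L = 20)
    p <- partition(mt$ids, sample(rep(c("A", "B"), each = 5)))
    snn_test(mt, p, n_perm = 60)$p_value
  })
  # under the null p is (discretely) uniform: its mean sits near 1/2
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.1), 0.3)
})
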