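test_that("a single lineage coalesces with no events", {
  gen <- sample_genealogy(constant_demography(50), c(pop1 = 1L))
  expect_equal(gen$n_tip, 1)
  expect_equal(tmrca(gen), 0)
  expect_equal(total_branch_length(gen), 0)
})

test_that("pair coalescence times match E[T2] = 2N (nuclear) and N/2
          (mtDNA)", {
  set.seed(41)
  dem <- constant_demography(80)
  t_nuc <- replicate(4000, tmrca(sample_genealogy(dem, c(pop1 = 2L),
                                                  "nuclear")))
  se <- sd(t_nuc) / sqrt(length(t_nuc))
  expect_lt(abs(mean(t_nuc) - 160), 3 * se)
  t_mt <- replicate(4000, tmrca(sample_genealogy(dem, c(pop1 = 2L),
                                                 "mtDNA")))
  se_mt <- sd(t_mt) / sqrt(length(t_mt))
  expect_lt(abs(mean(t_mt) - 40), 3 * se_mt)
  # the mtDNA/nuclear TMRCA ratio is 1/4
  ratio <- mean(t_mt) / mean(t_nuc)
  expect_gt(ratio, 0.22)
  expect_lt(ratio, 0.28)
})

test_that("total branch length matches 4N sum(1/i) for n = 10", {
  set.seed(42)
  dem <- constant_demography(100)
  tl <- replicate(2500, total_branch_length(
    sample_genealogy(dem, c(pop1 = 10L))))
  expected <- 4 * 100 * sum(1 / (1:9))
  expect_lt(abs(mean(tl) - expected), 3 * sd(tl) / sqrt(length(tl)))
})

test_that("every realization has exactly n - 1 coalescences, also across
          demes", {
  set.seed(43)
  dem <- demography(
    c("A", "B", "ANC"),
    list(A = data.frame(time = 0, size = 40),
         B = data.frame(time = c(0, 10), size = c(20, 60)),
         ANC = data.frame(time = 0, size = 100)),
    data.frame(time = 25, type = "merge", from = c("A", "B"),
               to = "ANC", to2 = NA, prob = NA))
  for (i in 1:20) {
    gen <- sample_genealogy(dem, c(A = 5L, B = 7L))
    expect_equal(length(gen$parent), 2 * 12 - 1)
    expect_equal(sum(gen$parent == 0), 1)  # single root
    expect_true(all(diff(sort(gen$time[13:23])) > 0))
  }
})

test_that("demography validation catches stranded lineages and events on
          emptied demes", {
  expect_error(demography(
    c("A", "B"),
    list(A = data.frame(time = 0, size = 10),
         B = data.frame(time = 0, size = 10))),
    "no merge events")
  expect_error(demography(
    c("A", "B", "C"),
    list(A = data.frame(time = 0, size = 10),
         B = data.frame(time = 0, size = 10),
         C = data.frame(time = 0, size = 10)),
    data.frame(time = 5, type = "merge", from = "A", to = "B",
               to2 = NA, prob = NA)),
    "root demes")
  expect_error(demography(
    c("A", "B"),
    list(A = data.frame(time = 0, size = 10),
         B = data.frame(time = 0, size = 10)),
    data.frame(time = c(5, 8), type = "merge", from = c("A", "A"),
               to = c("B", "B"), to2 = NA, prob = NA)),
    "emptied")
})

test_that("microsatellite mutation honours the rate and the stepwise
          model", {
  dem <- constant_demography(50)
  model0 <- mutation_model(mu_mic = 0)
  gen <- sample_genealogy(dem, c(pop1 = 8L))
  expect_true(all(mutate_microsat(gen, model0) == 20))
  # strict SMM on a fixed two-tip genealogy: mean squared difference
  # = 2 mu t (1 + P)/(1 - P)^2 with P = 0
  t_div <- 500
  fixed <- structure(list(parent = c(3L, 3L, 0L), time = c(0, 0, t_div),
                          n_tip = 2L, tip_deme = c("a", "a")),
                     class = "genealogy")
  mu <- 2e-3
  set.seed(44)
  d_smm <- replicate(4000, {
    st <- mutate_microsat(fixed, mutation_model(mu_mic = mu, p_gsm = 0,
                                                range = 2000))
    (st[1] - st[2])^2
  })
  expected <- 2 * mu * t_div
  expect_lt(abs(mean(d_smm) - expected),
            3 * sd(d_smm) / sqrt(length(d_smm)))
  # GSM inflates the step variance by (1+P)/(1-P)^2
  p_gsm <- 0.3
  d_gsm <- replicate(4000, {
    st <- mutate_microsat(fixed, mutation_model(mu_mic = mu, p_gsm = p_gsm,
                                                range = 2000))
    (st[1] - st[2])^2
  })
  expected_g <- 2 * mu * t_div * (1 + p_gsm) / (1 - p_gsm)^2
  expect_lt(abs(mean(d_gsm) - expected_g),
            3 * sd(d_gsm) / sqrt(length(d_gsm)))
})

test_that("sequence mutation matches the Watterson expectation and the
          transition limit", {
  dem <- constant_demography(100)
  model0 <- mutation_model(mu_mt = 0)
  gen <- sample_genealogy(dem, c(pop1 = 6L), "mtDNA")
  expect_equal(ncol(mutate_sequence(gen, model0, 100)$tips), 0)
  set.seed(45)
  mu <- 1e-4; L <- 400; n <- 16
  S <- replicate(2500, length(mutate_sequence(
    sample_genealogy(dem, c(pop1 = n), "mtDNA"),
    mutation_model(mu_mt = mu), L)$positions))
  theta <- 2 * (100 / 2) * mu * L
  expected <- theta * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
  # kappa -> infinity: only transitions, so each site stays within its
  # purine or pyrimidine pair
  res <- mutate_sequence(sample_genealogy(dem, c(pop1 = 20L), "mtDNA"),
                         mutation_model(mu_mt = 5e-4, kappa = 1e9), 200)
  for (s in seq_len(ncol(res$tips))) {
    states <- unique(res$tips[, s])
    expect_true(all(states %in% c(0L, 2L)) || all(states %in% c(1L, 3L)))
  }
})

test_that("simulate_dataset is reproducible and exchangeable across
          pseudo-populations", {
  design <- sampling_design(c("A", "B"), c(6, 6), c(6, 6), n_loci = 3,
                            mt_length = 100)
  dem <- demography(
    c("A", "B", "ANC"),
    list(A = data.frame(time = 0, size = 500),
         B = data.frame(time = 0, size = 500),
         ANC = data.frame(time = 0, size = 500)),
    data.frame(time = 1e-6, type = "merge", from = c("A", "B"),
               to = "ANC", to2 = NA, prob = NA))
  draw <- list(demography = dem, mutation = mutation_model())
  d1 <- simulate_dataset(draw, design, seed = 7)
  d2 <- simulate_dataset(draw, design, seed = 7)
  expect_identical(d1$genotypes$a1, d2$genotypes$a1)
  expect_identical(d1$haplotypes$seq, d2$haplotypes$seq)
  # panmictic scenario split into two pseudo-populations: theta centred
  # on 0
  set.seed(46)
  thetas <- replicate(200, {
    ds <- simulate_dataset(draw, design)
    wc_fstats(ds$genotypes, ds$partition)$theta
  })
  expect_lt(abs(mean(thetas, na.rm = TRUE)), 0.01)
})

test_that("a founder bottleneck depresses the M-ratio relative to constant
          size", {
  set.seed(47)
  design <- sampling_design("pop1", 12, 0, n_loci = 5, mt_length = 100)
  const <- constant_demography(5000)
  bneck <- demography("pop1",
                      list(pop1 = data.frame(time = c(0, 40, 60),
                                             size = c(5000, 25, 5000))))
  model <- mutation_model(mu_mic = 5e-4, p_gsm = 0.2)
  mgw_of <- function(dem) {
    raw <- finpop:::.sim_raw(dem, model, design)
    gt <- genotype_table(sprintf("i%02d", 1:12), paste0("L", 1:5),
                         raw$a1 + 10L, raw$a2 + 10L)
    garza_williamson_m(gt, partition(gt$ids, rep("p", 12)))$
      per_population$m_gw
  }
  m_const <- replicate(120, mgw_of(const))
  m_bneck <- replicate(120, mgw_of(bneck))
  wt <- wilcox.test(m_bneck, m_const, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("the M-ratio null test behaves at its extremes", {
  expect_error(m_gw_test(0.5, 10, 5, n_sims = 50), "unstable")
  r <- m_gw_test(1.0, n_ind = 10, n_loci = 4, n_sims = 150, seed = 1)
  expect_gt(r$p_value, 0.8)
  r2 <- m_gw_test(0.3, n_ind = 10, n_loci = 4, n_sims = 150, seed = 2)
  expect_lt(r2$p_value, 0.1)
})
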