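test_that("the three shipped sets have the required sizes and structure", {
  design <- tiny_design()
  s1 <- build_step1_topologies(design)
  expect_length(s1$scenarios, 10)
  expect_equal(names(s1$scenarios)[1], "SC1")
  expect_match(s1$scenarios$SC1$description, "trichotomy")
  s2 <- build_step2_sizechange(design)
  expect_length(s2$scenarios, 6)
  s3 <- build_step3_collapse(design)
  expect_length(s3$scenarios, 2)
})

test_that("the trichotomy realizes a single shared split time", {
  set.seed(51)
  s1 <- build_step1_topologies(tiny_design())
  for (i in 1:10) {
    d <- sample_prior(s1, "SC1")
    ev <- d$demography$events
    expect_equal(nrow(ev), 3)
    expect_equal(length(unique(ev$time)), 1)
    expect_true(all(ev$type == "merge"))
  }
})

test_that("every scenario of every set realizes a valid demography under
          prior fuzzing", {
  set.seed(52)
  design <- tiny_design()
  for (set in list(build_step1_topologies(design),
                   build_step2_sizechange(design),
                   build_step3_collapse(design))) {
    for (nm in names(set$scenarios)) {
      for (i in 1:25) {
        d <- sample_prior(set, nm)
        # demography() already validates; re-validate explicitly
        expect_silent(validate_demography(d$demography))
      }
    }
  }
})

test_that("parameter conditions hold in every accepted draw", {
  set.seed(53)
  s2 <- build_step2_sizechange(tiny_design())
  for (i in 1:50) {
    d <- sample_prior(s2, "SC3")
    expect_gt(d$params[["T_exp2"]], d$params[["T_isol2"]])
  }
  s3 <- build_step3_collapse(tiny_design())
  for (i in 1:50) {
    d <- sample_prior(s3, "SC2")
    expect_lte(d$params[["T_col"]], 50)  # <= 5 generations of 10 years
  }
})

test_that("unsatisfiable conditions raise a prior specification error", {
  sc <- scenario("bad",
                 params = list(list(name = "N", dist = "unif", min = 10,
                                    max = 20, unit = "ind")),
                 demes = "A",
                 sizes = list(A = list(list(time = "0", size = "N"))),
                 events = list(), conditions = "N > 100")
  set <- scenario_set(list(sc), sampling_design("A", 4, 4, 2, 100))
  expect_error(sample_prior(set, "bad", max_tries = 200),
               "unsatisfiable")
})

test_that("prior draws are seed-reproducible and uniform priors have the
          right mean", {
  s2 <- build_step2_sizechange(tiny_design())
  d1 <- sample_prior(s2, "SC1", seed = 99)
  d2 <- sample_prior(s2, "SC1", seed = 99)
  expect_identical(d1$params, d2$params)
  set.seed(54)
  draws <- replicate(3000, sample_prior(s2, "SC1")$params[["T_isol2"]])
  # uniform on [100, 5000]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2550), 3 * se)
})

test_that("forcing equal ancestral sizes nests the constant scenario
          inside the founder-bottleneck one", {
  set.seed(55)
  design <- tiny_design(n_loci = 4, mt_length = 150)
  s2 <- build_step2_sizechange(design)
  he_of <- function(dem, model) {
    raw <- finpop:::.sim_raw(dem, model, design)
    mean(finpop:::.ss_from_raw(raw, design)[c("XCSS_he", "PY_he", "TL_he")])
  }
  model <- mutation_model(mu_mic = 5e-4, p_gsm = 0.1, mu_mt = 2e-7)
  par_sc1 <- c(N_XCSS = 800, N_PY = 900, N_TL = 700, N_exp2 = 3000,
               T_isol2 = 1500)
  par_sc3 <- c(par_sc1, N_anc2 = 3000, N_founder = 3000, T_exp2 = 9000,
               DB = 200)
  dem1 <- realize_scenario(s2$scenarios$SC1, par_sc1, 10)
  dem3 <- realize_scenario(s2$scenarios$SC3, par_sc3, 10)
  he1 <- replicate(250, he_of(dem1, model))
  he3 <- replicate(250, he_of(dem3, model))
  ks <- suppressWarnings(ks.test(he1, he3))
  expect_gt(ks$p.value, 0.01)
})

test_that("collapse datasets carry a lower M-ratio than constant-size
          ones", {
  set.seed(56)
  design <- tiny_design(n_loci = 4, mt_length = 150)
  s3 <- build_step3_collapse(design)
  base <- c(N_XCSS = 2000, N_PY = 2000, N_TL = 2000, N_exp2 = 5000,
            N_anc2 = 15000, N_founder = 100, T_isol2 = 1000, T_exp2 = 4000,
            DB = 100)
  par1 <- base
  par2 <- c(base, T_col = 50, f_XCSS = 0.02, f_PY = 0.02, f_TL = 0.02)
  model <- mutation_model(mu_mic = 5e-4, p_gsm = 0.1, mu_mt = 2e-7)
  mgw_of <- function(dem) {
    raw <- finpop:::.sim_raw(dem, model, design)
    ss <- finpop:::.ss_from_raw(raw, design)
    mean(ss[c("XCSS_mgw", "PY_mgw", "TL_mgw")])
  }
  dem1 <- realize_scenario(s3$scenarios$SC1, par1, 10)
  dem2 <- realize_scenario(s3$scenarios$SC2, par2, 10)
  m1 <- replicate(300, mgw_of(dem1))
  m2 <- replicate(300, mgw_of(dem2))
  expect_lt(wilcox.test(m2, m1, alternative = "less")$p.value, 0.01)
})

test_that("scenario sets serialize to YAML and back with full fidelity", {
  set <- build_step2_sizechange(tiny_design())
  y <- scenario_set_to_yaml(set)
  set2 <- scenario_set_from_yaml(y)
  expect_equal(names(set2$scenarios), names(set$scenarios))
  expect_equal(set2$design$n_diploid, set$design$n_diploid)
  expect_equal(set2$mut_prior$mu_mic, set$mut_prior$mu_mic)
  # identical draws under the same seed prove the templates survived
  d1 <- sample_prior(set, "SC3", seed = 77)
  d2 <- sample_prior(set2, "SC3", seed = 77)
  expect_identical(d1$params, d2$params)
  expect_equal(d1$demography$sizes, d2$demography$sizes)
  # and a file round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  scenario_set_to_yaml(set, f)
  set3 <- scenario_set_from_yaml(f)
  expect_identical(sample_prior(set3, "SC3", seed = 77)$params, d1$params)
})
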