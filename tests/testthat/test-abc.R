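test_that("rejection selection equals a brute-force full sort", {
  set.seed(61)
  tab <- fake_reference_table(500, list(S1 = 0, S2 = 1), seed = 2)
  obs <- setNames(rnorm(4), colnames(tab$stats))
  sel <- rejection_select(obs, tab, 0.05)
  # independent brute force: standardize by MAD, full sort
  scale <- apply(tab$stats, 2, mad)
  d <- sqrt(colSums(((t(tab$stats) - obs) / scale)^2))
  ord <- order(d)[seq_len(ceiling(0.05 * nrow(tab$stats)))]
  expect_identical(sel$index, ord)
  expect_equal(sel$distance, d[ord])
  # tolerance 1 returns every row
  expect_length(rejection_select(obs, tab, 1)$index, 1000)
  # a row identical to the observation ranks first at distance 0
  obs2 <- tab$stats[137, ]
  sel2 <- rejection_select(obs2, tab, 0.01)
  expect_equal(sel2$index[1], 137)
  expect_equal(sel2$distance[1], 0)
})

test_that("zero-variance statistics are dropped with a warning", {
  tab <- fake_reference_table(100, list(S1 = 0, S2 = 1), seed = 3)
  tab$stats[, 2] <- 5
  obs <- setNames(c(0, 5, 0, 0), colnames(tab$stats))
  expect_warning(rejection_select(obs, tab, 0.1), "zero-variance")
})

test_that("logistic model choice separates separable scenarios and stays
          agnostic on identical ones", {
  # disjoint supports
  tab <- fake_reference_table(300, list(S1 = 0, S2 = 12), sd = 1,
                              seed = 4)
  obs <- setNames(rep(12, 4) + rnorm(4, 0, 0.5), colnames(tab$stats))
  sel <- rejection_select(obs, tab, 0.2)
  mc <- suppressWarnings(model_choice_logistic(tab, sel, obs))
  expect_equal(sum(mc$prob), 1, tolerance = 1e-9)
  expect_gt(mc$prob[["S2"]], 0.99)
  expect_equal(mc$best, "S2")
  # identical generating processes: probabilities hover around 1/2
  set.seed(65)
  probs <- replicate(20, {
    tab0 <- fake_reference_table(150, list(S1 = 0, S2 = 0),
                                 seed = sample.int(1e6, 1))
    obs0 <- setNames(rnorm(4), colnames(tab0$stats))
    sel0 <- rejection_select(obs0, tab0, 0.3)
    suppressWarnings(model_choice_logistic(tab0, sel0, obs0))$prob[["S1"]]
  })
  expect_gt(mean(probs), 0.3)
  expect_lt(mean(probs), 0.7)
})

test_that("random-forest model choice conserves votes and calibrates its
          prior error", {
  tab <- fake_reference_table(300, list(S1 = 0, S2 = 12), seed = 5)
  obs <- setNames(rep(0, 4), colnames(tab$stats))
  expect_error(model_choice_rf(tab, obs, n_trees = 10), "refuse")
  rf <- model_choice_rf(tab, obs, n_trees = 200, seed = 6)
  expect_equal(sum(rf$votes), 200)
  expect_equal(rf$best, "S1")
  expect_lt(rf$prior_error, 0.05)
  expect_gt(rf$post_prob, 0.9)
  # indistinguishable scenarios: prior error ~ 1/2
  tab0 <- fake_reference_table(300, list(S1 = 0, S2 = 0), seed = 7)
  rf0 <- model_choice_rf(tab0, obs, n_trees = 200, seed = 8)
  expect_gt(rf0$prior_error, 0.4)
  expect_lt(rf0$prior_error, 0.6)
})

test_that("reference tables are balanced, deterministic and mergeable", {
  set <- two_pop_set(100, 5000, 100, 5000)
  tab <- build_reference_table(set, 25, seed = 9)
  expect_equal(as.vector(table(tab$scenario)), c(25, 25))
  expect_equal(nrow(tab$stats), 50)
  tab2 <- build_reference_table(set, 25, seed = 9)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
  merged <- bind_reference_tables(tab, tab2)
  expect_equal(nrow(merged$stats), 100)
  sub <- subset_reference_table(tab, "S1")
  expect_equal(nrow(sub$stats), 25)
  expect_true(all(sub$scenario == "S1"))
})

test_that("SS distributions are stable across independent seeds", {
  set <- two_pop_set(500, 2000, 500, 2000)
  t1 <- build_reference_table(set, 60, seed = 11, scenarios = "S1")
  t2 <- build_reference_table(set, 60, seed = 120011, scenarios = "S1")
  for (stat in c("A_he", "A_k")) {
    p <- t.test(t1$stats[, stat], t2$stats[, stat])$p.value
    expect_gt(p, 0.001)
  }
})

test_that("error calibration recovers the diagonal structure of the truth",
{
  # identical scenarios: every cell of the confusion matrix ~ 1/2
  set.seed(66)
  set_id <- two_pop_set(100, 5000, 100, 5000)
  tab <- build_reference_table(set_id, 120, seed = 13)
  cal <- suppressWarnings(calibrate_errors(set_id, tab, 25, 0.2,
                                           seed = 14))
  expect_equal(dim(cal$confusion), c(2, 2))
  expect_equal(unname(rowSums(cal$confusion)), c(1, 1))
  expect_gt(cal$prior_error, 0.3)
  bt <- binom.test(round(sum(diag(cal$confusion) * 25)), 50, 0.5)
  expect_gt(bt$p.value, 0.01)
  # separable scenarios: near-perfect assignment
  set_sep <- two_pop_set(4000, 20000, 10, 60)
  tab2 <- build_reference_table(set_sep, 120, seed = 15)
  cal2 <- suppressWarnings(calibrate_errors(set_sep, tab2, 25, 0.2,
                                            seed = 16))
  expect_lt(cal2$prior_error, 0.1)
  expect_true(all(diag(cal2$confusion) > 0.85))
  expect_true(all(cal2$type1 < 0.15))
  expect_true(all(cal2$type2 < 0.15))
})

test_that("parameter estimation is exact on degenerate posteriors and
          respects prior bounds", {
  set <- two_pop_set(100, 5000, 100, 5000)
  tab <- build_reference_table(set, 80, seed = 17)
  sub <- subset_reference_table(tab, "S1")
  # force a degenerate parameter: overwrite draws with a constant
  for (i in seq_along(sub$params)) sub$params[[i]]["N_A"] <- 777
  obs <- sub$stats[1, ]
  rej <- suppressWarnings(rejection_select(obs, sub, 1))
  post <- estimate_parameters(set, "S1", sub, rej, obs,
                              min_selected = 20)
  s <- post$summary
  expect_equal(s$median[s$parameter == "N_A"], 777)
  expect_equal(s$q97.5[s$parameter == "N_A"], 777)
  # all adjusted draws stay inside the prior box
  expect_true(all(post$adjusted[, "N_B"] >= 100 - 1e-6))
  expect_true(all(post$adjusted[, "N_B"] <= 5000 + 1e-6))
  expect_true(all(post$adjusted[, "mu_mic"] >= 1e-4 * (1 - 1e-6)))
  # too few accepted draws is an explicit error
  expect_error(estimate_parameters(set, "S1", sub,
                                   list(index = 1:5,
                                        distance = rep(1, 5)), obs),
               "tolerance")
})

test_that("posterior predictive checks calibrate on well-specified data
          and flag a shifted statistic", {
  set.seed(67)
  set <- two_pop_set(500, 3000, 500, 3000)
  tab <- build_reference_table(set, 150, seed = 18, scenarios = "S1")
  d <- sample_prior(set, "S1", seed = 19)
  raw <- finpop:::.sim_raw(d$demography, d$mutation, set$design)
  obs <- finpop:::.ss_from_raw(raw, set$design)
  sub <- subset_reference_table(tab, "S1")
  rej <- suppressWarnings(rejection_select(obs, sub, 0.3))
  post <- estimate_parameters(set, "S1", sub, rej, obs, min_selected = 20)
  ppc <- posterior_predictive_check(set, post, obs, n_sims = 60,
                                    seed = 20)
  # the model generated the data: few statistics should be flagged
  expect_lt(mean(ppc$flagged), 0.2)
  # shift one statistic far outside the simulated range
  obs_shift <- obs
  obs_shift["A_he"] <- obs["A_he"] + 10 * sd(sub$stats[, "A_he"])
  ppc2 <- posterior_predictive_check(set, post, obs_shift, n_sims = 60,
                                     seed = 21)
  expect_true(ppc2$flagged[ppc2$statistic == "A_he"])
  expect_lt(ppc2$p_value[ppc2$statistic == "A_he"], 0.05)
})
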