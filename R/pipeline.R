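#' @name pipeline
#' @title Config-driven orchestration of the full analysis
#' @description `run_stats()` produces the diversity/differentiation
#'   report (the Table-1/2/3 layout of the study: per-cluster
#'   microsatellite and mtDNA diversity, pairwise differentiation with
#'   Bonferroni correction, LD-Ne estimates) and `run_abc()` runs the
#'   three nested ABC steps (branching order, size changes, recent
#'   collapse) with model choice by both LDA-logistic regression and
#'   random forest, error calibration, parameter posteriors and posterior
#'   predictive checks. All randomness flows from the config seed and
#'   every report embeds the seed and a config fingerprint.
NULL

#' Analysis configuration
#'
#' @param rarefaction_individuals Diploid individuals for allelic-richness
#'   rarefaction (default 26, i.e. 52 gene copies).
#' @param private_rarefaction_individuals Diploid individuals for private
#'   allelic richness (default 3).
#' @param n_perm Permutations for F_IS / F_ST tests (default 10^4).
#' @param n_boot Bootstrap resamples for F_ST CIs (default 10^4).
#' @param snn_perm Snn permutations (default 10^3).
#' @param mgw_sims Coalescent simulations for the M-ratio null (default
#'   10^4; the study-scale value is 10^6).
#' @param tajima_sims Coalescent simulations for Tajima's D (default
#'   10^4).
#' @param p_crit LD-Ne rare-allele screen (default 0.02).
#' @param gen_time Generation time in years (default 10).
#' @param abc_pops Populations entering the ABC analysis (default the
#'   three distinct clusters `XCSS`, `PY`, `TL`).
#' @param n_per_scenario Reference-table rows per scenario (default 1000;
#'   the study-scale value is 10^6).
#' @param tolerance Rejection tolerance (default 0.02).
#' @param n_trees Random-forest size (default 500).
#' @param n_pods Held-out PODs per scenario for error calibration
#'   (default 50; 0 skips calibration).
#' @param ppc_sims Posterior predictive simulations (default 100).
#' @param seed Master seed for every stochastic component.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(rarefaction_individuals = 26,
                            private_rarefaction_individuals = 3,
                            n_perm = 10000, n_boot = 10000,
                            snn_perm = 1000, mgw_sims = 10000,
                            tajima_sims = 10000, p_crit = 0.02,
                            gen_time = 10,
                            abc_pops = c("XCSS", "PY", "TL"),
                            n_per_scenario = 1000, tolerance = 0.02,
                            n_trees = 500, n_pods = 50, ppc_sims = 100,
                            seed = 1) {
  cfg <- list(rarefaction_individuals = rarefaction_individuals,
              private_rarefaction_individuals =
                private_rarefaction_individuals,
              n_perm = n_perm, n_boot = n_boot, snn_perm = snn_perm,
              mgw_sims = mgw_sims, tajima_sims = tajima_sims,
              p_crit = p_crit, gen_time = gen_time, abc_pops = abc_pops,
              n_per_scenario = n_per_scenario, tolerance = tolerance,
              n_trees = n_trees, n_pods = n_pods, ppc_sims = ppc_sims,
              seed = as.integer(seed))
  stopifnot(all(unlist(cfg[c("n_perm", "n_boot", "snn_perm", "mgw_sims",
                             "tajima_sims", "n_per_scenario", "n_trees",
                             "ppc_sims")]) >= 0))
  structure(cfg, class = "analysis_config")
}

.config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns"))))
}

#' Diversity and differentiation report
#'
#' Applies the individual-inclusion filter, then computes the per-cluster
#' microsatellite summaries (sample size, missingness, rarefied and
#' private allelic richness, observed/expected heterozygosity, F_IS with
#' permutation test, M-ratio with coalescent null test), the mtDNA
#' diversity summaries per cluster and overall, pairwise differentiation
#' for both markers with Bonferroni-corrected significance, and the LD-Ne
#' estimates per cluster and pooled.
#'
#' @param geno A [genotype_table()].
#' @param mt A [haplotype_alignment()] or `NULL`.
#' @param part Partition data frame from [partition()].
#' @param config An [analysis_config()].
#' @return An object of class `stats_report` (a list of data frames:
#'   `filter`, `microsat`, `mtdna`, `fst_microsat`, `fst_mtdna`, `ldne`)
#'   with the seed and config fingerprint attached.
#' @export
run_stats <- function(geno, mt, part, config = analysis_config()) {
  set.seed(config$seed)
  missing_part <- setdiff(part$id, c(geno$ids, if (!is.null(mt)) mt$ids))
  if (length(missing_part))
    stop("validation error: partition labels unknown individuals: ",
         paste(head(missing_part, 10), collapse = ", "))
  flt <- filter_individuals(geno, mt)
  geno <- flt$genotypes
  micro <- microsat_diversity(geno, part, n_perm = config$n_perm)
  g_ar <- 2 * config$rarefaction_individuals
  ar <- tryCatch(allelic_richness(geno, part, g_ar)$per_population,
                 error = function(e) {
                   warning("allelic richness skipped: ", conditionMessage(e))
                   NULL
                 })
  g_pa <- 2 * config$private_rarefaction_individuals
  pa <- tryCatch(private_allelic_richness(geno, part, g_pa)$per_population,
                 error = function(e) {
                   warning("private allelic richness skipped: ",
                           conditionMessage(e))
                   NULL
                 })
  if (!is.null(ar)) micro <- merge(micro, ar, by = "population", sort = FALSE)
  if (!is.null(pa)) micro <- merge(micro, pa, by = "population", sort = FALSE)
  popv <- .pop_of(geno$ids, part)
  micro$m_gw_p <- vapply(micro$population, function(p) {
    n_ind <- sum(!is.na(popv) & popv == p)
    m_gw_test(micro$m_gw[micro$population == p], n_ind,
              length(geno$loci), n_sims = max(100, config$mgw_sims),
              seed = config$seed + match(p, micro$population))$p_value
  }, numeric(1))
  micro$fis_sig <- .stars(micro$fis_p)
  micro$m_gw_sig <- .stars(micro$m_gw_p)

  mtdna <- NULL
  if (!is.null(mt)) {
    mtdna <- sequence_diversity(mt, part)
    mpop <- .pop_of(mt$ids, part)
    mtdna$tajima_p <- vapply(seq_len(nrow(mtdna)), function(k) {
      p <- mtdna$population[k]
      idx <- if (p == "Total") which(!is.na(mpop)) else
        which(!is.na(mpop) & mpop == p)
      if (length(idx) < 4 || is.na(mtdna$S[k]) || mtdna$S[k] == 0)
        return(NA_real_)
      tajima_d_test(mt[idx], n_sims = config$tajima_sims,
                    seed = config$seed + 100 + k)$p_value
    }, numeric(1))
    mtdna$tajima_sig <- .stars(mtdna$tajima_p)
  }

  fst_mic <- pairwise_fst_microsat(geno, part, n_boot = config$n_boot,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 7)
  fst_mic$p_bonferroni <- p.adjust(fst_mic$p_value, "bonferroni")
  fst_mic$sig <- .stars(fst_mic$p_bonferroni)
  fst_mt <- NULL
  if (!is.null(mt)) {
    fst_mt <- pairwise_fst_mtdna(mt, part, n_perm = config$snn_perm,
                                 seed = config$seed + 8)
    fst_mt$p_bonferroni <- p.adjust(fst_mt$p_value, "bonferroni")
    fst_mt$sig <- .stars(fst_mt$p_bonferroni)
  }

  ldne <- do.call(rbind, lapply(
    c(levels(part$population), "Total"), function(p) {
      idx <- if (p == "Total") which(!is.na(popv)) else
        which(!is.na(popv) & popv == p)
      est <- tryCatch(ldne_estimate(geno[idx], p_crit = config$p_crit),
                      error = function(e) NULL)
      if (is.null(est))
        return(data.frame(population = p, ne = NA, ci_low = NA,
                          ci_high = NA, ci_jack_low = NA,
                          ci_jack_high = NA, n_comparisons = NA,
                          harmonic_s = NA))
      data.frame(population = p, ne = est$ne,
                 ci_low = est$ci_parametric[1],
                 ci_high = est$ci_parametric[2],
                 ci_jack_low = est$ci_jackknife[1],
                 ci_jack_high = est$ci_jackknife[2],
                 n_comparisons = est$n_comparisons,
                 harmonic_s = est$harmonic_s)
    }))

  structure(list(filter = flt$report, microsat = micro, mtdna = mtdna,
                 fst_microsat = fst_mic, fst_mtdna = fst_mt, ldne = ldne,
                 seed = config$seed,
                 fingerprint = .config_fingerprint(config)),
            class = "stats_report")
}

#' Write a stats report to CSV + JSON
#' @param report A `stats_report` from [run_stats()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("filter", "microsat", "mtdna", "fst_microsat", "fst_mtdna",
               "ldne")) {
    if (!is.null(report[[nm]]))
      write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(report[!vapply(report, is.null, logical(1))], function(x) x),
    file.path(dir, "stats_report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

.abc_design_from_data <- function(geno, mt, part, pops) {
  popv <- .pop_of(geno$ids, part)
  n_dip <- vapply(pops, function(p) sum(!is.na(popv) & popv == p),
                  integer(1))
  if (!is.null(mt)) {
    mpop <- .pop_of(mt$ids, part)
    n_mt <- vapply(pops, function(p) sum(!is.na(mpop) & mpop == p),
                   integer(1))
    mt_len <- length(usable_sites(mt))
  } else {
    n_mt <- pmin(n_dip, 0L)
    mt_len <- 1L
  }
  sampling_design(pops, n_dip, pmin(n_mt, n_dip), length(geno$loci),
                  mt_len)
}

.run_abc_step <- function(set, obs, config, step_seed) {
  table <- build_reference_table(set, config$n_per_scenario,
                                 seed = step_seed)
  rej <- suppressWarnings(rejection_select(obs, table, config$tolerance))
  logit <- suppressWarnings(model_choice_logistic(table, rej, obs))
  rf <- model_choice_rf(table, obs, n_trees = config$n_trees,
                        seed = step_seed + 1)
  errors <- NULL
  if (config$n_pods > 0)
    errors <- calibrate_errors(set, table, config$n_pods,
                               config$tolerance, seed = step_seed + 2)
  # the forest vote decides the step winner (it classifies on the full
  # reference table and is markedly more robust than the logistic path at
  # desk-scale table sizes); the logistic probabilities are reported with
  # their CIs alongside
  list(table = table, rejection = rej, logistic = logit, rf = rf,
       errors = errors, winner = rf$best,
       n_scenarios = length(set$scenarios))
}

#' Three-step nested ABC analysis
#'
#' Step 1 chooses the branching order among ten topologies; step 2 tests
#' six nested size-change scenarios on the winning topology; step 3 asks
#' whether an additional recent collapse in each population improves the
#' fit, then estimates parameter posteriors under the final winner and
#' runs posterior predictive checks under both step-3 scenarios (so a
#' misfit of the constant-size alternative, typically on the M-ratio
#' statistics, is visible). Steps condition sequentially on the previous
#' winner and winners are never revisited.
#'
#' @param geno A [genotype_table()].
#' @param mt A [haplotype_alignment()] or `NULL`.
#' @param part Partition data frame.
#' @param config An [analysis_config()].
#' @return An object of class `abc_report`: `step1`, `step2`, `step3`
#'   (each with model-choice results and error calibration), `posterior`,
#'   `ppc`, `ppc_alternative`, plus seed and fingerprint.
#' @export
run_abc <- function(geno, mt, part, config = analysis_config()) {
  pops <- config$abc_pops
  design <- .abc_design_from_data(geno, mt, part, pops)
  obs <- observed_ss(geno, mt, part, pops)
  base_seed <- config$seed

  step1 <- .run_abc_step(build_step1_topologies(design), obs, config,
                         base_seed + 10000)
  step2 <- .run_abc_step(build_step2_sizechange(design), obs, config,
                         base_seed + 20000)
  set3 <- build_step3_collapse(design, base = step2$winner)
  step3 <- .run_abc_step(set3, obs, config, base_seed + 30000)

  winner <- step3$winner
  # parameters are estimated from the winner's own simulations: rejection
  # restricted to that scenario's reference rows
  fit_scenario <- function(name) {
    sub <- subset_reference_table(step3$table, name)
    rej <- suppressWarnings(rejection_select(obs, sub,
                                             config$tolerance * 2))
    tryCatch(
      estimate_parameters(set3, name, sub, rej, obs, min_selected = 20),
      error = function(e) {
        warning("parameter estimation failed for ", name, ": ",
                conditionMessage(e))
        NULL
      })
  }
  post <- fit_scenario(winner)
  ppc <- NULL
  ppc_alt <- NULL
  if (!is.null(post))
    ppc <- posterior_predictive_check(set3, post, obs,
                                      n_sims = config$ppc_sims,
                                      seed = base_seed + 40000)
  alt <- setdiff(names(set3$scenarios), winner)[1]
  post_alt <- fit_scenario(alt)
  if (!is.null(post_alt))
    ppc_alt <- posterior_predictive_check(set3, post_alt, obs,
                                          n_sims = config$ppc_sims,
                                          seed = base_seed + 50000)
  strip <- function(s) s[setdiff(names(s), "table")]
  structure(list(step1 = strip(step1), step2 = strip(step2),
                 step3 = strip(step3), winner = winner,
                 posterior = post, ppc = ppc, ppc_alternative = ppc_alt,
                 observed_ss = obs, design = design, seed = config$seed,
                 fingerprint = .config_fingerprint(config)),
            class = "abc_report")
}

#' Write an ABC report to JSON
#' @param report An `abc_report` from [run_abc()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_abc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- list(
    winner = report$winner,
    seed = report$seed, fingerprint = report$fingerprint,
    observed_ss = as.list(report$observed_ss))
  for (st in c("step1", "step2", "step3")) {
    s <- report[[st]]
    slim[[st]] <- list(
      n_scenarios = s$n_scenarios, winner = s$winner,
      logistic_prob = as.list(s$logistic$prob),
      rf_best = s$rf$best, rf_post_prob = s$rf$post_prob,
      rf_post_prob_sd = s$rf$post_prob_sd,
      rf_prior_error = s$rf$prior_error,
      calibration = if (!is.null(s$errors)) list(
        prior_error = s$errors$prior_error,
        type1 = as.list(s$errors$type1),
        type2 = as.list(s$errors$type2)) else NULL)
  }
  if (!is.null(report$posterior))
    slim$posterior <- report$posterior$summary
  if (!is.null(report$ppc)) slim$ppc <- report$ppc
  if (!is.null(report$ppc_alternative))
    slim$ppc_alternative <- report$ppc_alternative
  jsonlite::write_json(slim, file.path(dir, "abc_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
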