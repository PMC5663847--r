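#' @name synthetic-data
#' @title Study-emulating synthetic datasets with known truth
#' @description Generates datasets with the dimensions of the porpoise
#'   study (four clusters of diploid microsatellite genotypes, a partial
#'   mtDNA alignment, missing genotypes) under a fully specified
#'   demographic truth, so that every stage of the pipeline can be
#'   exercised and validated without the original supplementary data.
NULL

#' Fixed-truth configuration for the synthetic generator
#'
#' Defaults mirror the fitted demographic history: a large ancestral
#' (marine) population of 18,700, a founder bottleneck of 50 diploids
#' lasting 100 years at 3,400 years BP, expansion to 5,660, a trichotomous
#' split 1,030 years BP into daughters of 2,000 (the admixed group drawing
#' ancestry from all three), and a recent collapse 50 years ago leaving 2%
#' of the pre-collapse sizes.
#'
#' @param scenario `"collapse"` (default) or `"constant"` (no recent
#'   collapse).
#' @param params Named list overriding any of the default truth
#'   parameters: `N_anc2`, `N_founder`, `DB`, `N_exp2`, `T_exp2`,
#'   `T_isol2`, `N_daughter`, `T_col`, `f_remnant`, `T_adm`, plus mutation
#'   parameters `mu_mic`, `p_gsm`, `mu_mt`, `kappa`.
#' @param pops Population names (default `PY`, `TL`, `XCSS`, `Admix`).
#' @param n_diploid Diploid sample sizes (default 58/17/17/53).
#' @param n_mt_total Total mtDNA sequences kept after uniform subsampling
#'   (default 129).
#' @param n_loci,mt_length Marker dimensions (default 11 loci, 597 bp).
#' @param missing_frac Per-cell genotype missingness (default 0.05; must
#'   be in `[0, 0.5]`).
#' @param gen_time Generation time in years (default 10).
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(scenario = c("collapse", "constant"),
                         params = list(),
                         pops = c("PY", "TL", "XCSS", "Admix"),
                         n_diploid = c(58, 17, 17, 53),
                         n_mt_total = 129, n_loci = 11, mt_length = 597,
                         missing_frac = 0.05, gen_time = 10) {
  scenario <- match.arg(scenario)
  stopifnot(missing_frac >= 0, missing_frac <= 0.5,
            n_mt_total <= sum(n_diploid))
  defaults <- list(N_anc2 = 18700, N_founder = 50, DB = 100,
                   N_exp2 = 5660, T_exp2 = 3400, T_isol2 = 1030,
                   N_daughter = 2000, T_col = 50, f_remnant = 0.02,
                   T_adm = 100, mu_mic = 5e-4, p_gsm = 0.15,
                   mu_mt = 4e-7, kappa = 10)
  defaults[names(params)] <- params
  p <- defaults
  if (p$T_col >= p$T_isol2 || p$T_adm >= p$T_isol2)
    stop("collapse/admixture times must predate the split time")
  structure(list(scenario = scenario, params = p, pops = pops,
                 n_diploid = as.integer(n_diploid),
                 n_mt_total = as.integer(n_mt_total),
                 n_loci = as.integer(n_loci),
                 mt_length = as.integer(mt_length),
                 missing_frac = missing_frac, gen_time = gen_time),
            class = "truth_config")
}

# demography of the synthetic truth: trichotomy of the three distinct
# populations plus an admixed group joining them (major ancestry from the
# first population), founder bottleneck in the ancestor
.truth_demography <- function(truth) {
  p <- truth$params
  gt <- truth$gen_time
  pops <- truth$pops
  stopifnot(length(pops) == 4)
  core <- pops[1:3]
  adm <- pops[4]
  daughter_size <- function() {
    if (truth$scenario == "collapse")
      data.frame(time = c(0, p$T_col / gt),
                 size = c(max(1, p$f_remnant * p$N_daughter),
                          p$N_daughter))
    else data.frame(time = 0, size = p$N_daughter)
  }
  sizes <- c(setNames(lapply(c(core, adm, "AdmixB"), function(d)
    daughter_size()), c(core, adm, "AdmixB")),
    list(ANC = data.frame(
      time = c(0, p$T_exp2 / gt, (p$T_exp2 + p$DB) / gt),
      size = c(p$N_exp2, p$N_founder, p$N_anc2))))
  events <- rbind(
    data.frame(time = p$T_adm / gt, type = "admix", from = adm,
               to = core[1], to2 = "AdmixB", prob = 0.5,
               stringsAsFactors = FALSE),
    data.frame(time = p$T_adm / gt, type = "admix", from = "AdmixB",
               to = core[2], to2 = core[3], prob = 0.5,
               stringsAsFactors = FALSE),
    data.frame(time = p$T_isol2 / gt, type = "merge", from = core,
               to = "ANC", to2 = NA, prob = NA, stringsAsFactors = FALSE))
  demography(c(core, adm, "AdmixB", "ANC"), sizes, events, gen_time = gt)
}

#' Generate a study-like synthetic dataset
#'
#' Simulates the full two-marker dataset under the truth configuration,
#' applies uniform random genotype missingness, subsamples the mtDNA
#' alignment uniformly without replacement, and returns the same
#' containers observed data use, together with the truth record.
#'
#' @param truth A [truth_config()].
#' @param seed Optional integer seed (fixed seed gives an identical
#'   dataset).
#' @return List with `genotypes`, `haplotypes`, `partition` and `truth`
#'   (the configuration plus realized dimensions).
#' @export
generate_study_like <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- sampling_design(truth$pops, truth$n_diploid, truth$n_diploid,
                            truth$n_loci, truth$mt_length)
  dem <- .truth_demography(truth)
  model <- mutation_model(mu_mic = truth$params$mu_mic,
                          p_gsm = truth$params$p_gsm,
                          range = design$allele_range,
                          mu_mt = truth$params$mu_mt,
                          kappa = truth$params$kappa)
  ds <- simulate_dataset(list(demography = dem, mutation = model), design)
  gt <- ds$genotypes
  if (truth$missing_frac > 0) {
    drop <- matrix(runif(length(gt$a1)) < truth$missing_frac,
                   nrow = nrow(gt$a1))
    gt$a1[drop] <- NA; gt$a2[drop] <- NA
  }
  keep_mt <- sort(sample(length(ds$haplotypes$ids), truth$n_mt_total))
  mt <- ds$haplotypes[keep_mt]
  list(genotypes = gt, haplotypes = mt, partition = ds$partition,
       truth = list(config = truth, n_individuals = length(gt$ids),
                    n_mt = length(mt$ids)))
}

#' Scenario-choice and parameter-recovery experiment
#'
#' Repeatedly simulates datasets under a known truth taken from a scenario
#' of `set`, analyses each with the ABC machinery against a (shared)
#' reference table, and reports how often the true scenario wins together
#' with per-parameter bias, RMSE and empirical coverage of the 90% and 95%
#' posterior intervals.
#'
#' @param set A [scenario_set()].
#' @param true_scenario Name of the generating scenario in `set`.
#' @param true_params Named vector of generating parameter values
#'   (including `mu_mic`, `p_gsm`, `mu_mt`, `kappa`).
#' @param n_replicates Number of simulated observed datasets.
#' @param table Optional prebuilt `reference_table`; built with
#'   `n_per_scenario` rows per scenario otherwise.
#' @param n_per_scenario Reference-table size per scenario when `table`
#'   is `NULL`.
#' @param tolerance Rejection tolerance.
#' @param seed Integer seed.
#' @param estimate Also run parameter estimation per replicate (default
#'   `TRUE`).
#' @return List with `selection` (data frame per replicate) and
#'   `parameters` (per-parameter bias/RMSE/coverage, when estimated).
#' @export
recovery_experiment <- function(set, true_scenario, true_params,
                                n_replicates = 50, table = NULL,
                                n_per_scenario = 1000, tolerance = 0.05,
                                seed = 1, estimate = TRUE) {
  if (is.null(table))
    table <- build_reference_table(set, n_per_scenario, seed = seed)
  sc <- set$scenarios[[true_scenario]]
  design <- set$design
  model <- mutation_model(mu_mic = true_params[["mu_mic"]],
                          p_gsm = true_params[["p_gsm"]],
                          range = design$allele_range,
                          mu_mt = true_params[["mu_mt"]],
                          kappa = true_params[["kappa"]])
  dem <- realize_scenario(sc, true_params, set$gen_time)
  sel_rows <- list()
  est_rows <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer((seed + 97003 + r * 131) %% .Machine$integer.max))
    raw <- .sim_raw(dem, model, design)
    obs <- .ss_from_raw(raw, design)
    rej <- suppressWarnings(rejection_select(obs, table, tolerance))
    mc <- suppressWarnings(model_choice_logistic(table, rej, obs))
    sel_rows[[r]] <- data.frame(replicate = r, best = mc$best,
                                prob_true = mc$prob[[true_scenario]],
                                correct = mc$best == true_scenario,
                                stringsAsFactors = FALSE)
    if (estimate) {
      sub <- subset_reference_table(table, true_scenario)
      rej_sub <- suppressWarnings(rejection_select(obs, sub, tolerance))
      post <- tryCatch(
        estimate_parameters(set, true_scenario, sub, rej_sub, obs,
                            min_selected = 20),
        error = function(e) NULL)
      if (!is.null(post)) {
        s <- post$summary
        s$replicate <- r
        est_rows[[length(est_rows) + 1]] <- s
      }
    }
  }
  selection <- do.call(rbind, sel_rows)
  parameters <- NULL
  if (length(est_rows)) {
    est <- do.call(rbind, est_rows)
    est$truth <- unname(true_params[est$parameter])
    est <- est[!is.na(est$truth), ]
    parameters <- do.call(rbind, lapply(split(est, est$parameter),
                                        function(d) {
      data.frame(parameter = d$parameter[1],
                 truth = d$truth[1],
                 rel_bias_median = mean((d$median - d$truth) / d$truth),
                 rmse = sqrt(mean((d$median - d$truth)^2)),
                 coverage90 = mean(d$q5 <= d$truth & d$truth <= d$q95),
                 coverage95 = mean(d$q2.5 <= d$truth & d$truth <= d$q97.5),
                 median_of_medians = median(d$median),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(parameters) <- NULL
  }
  list(selection = selection, parameters = parameters,
       fraction_correct = mean(selection$correct))
}
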