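# tiny shared fixtures, all built in code

tiny_design <- function(n_loci = 5, mt_length = 300) {
  sampling_design(c("XCSS", "PY", "TL"), c(8, 10, 9), c(8, 10, 9),
                  n_loci = n_loci, mt_length = mt_length)
}

study_design <- function() {
  sampling_design(c("XCSS", "PY", "TL"), c(16, 58, 17), c(16, 56, 17),
                  n_loci = 11, mt_length = 597)
}

random_genotype_table <- function(n = 10, L = 4, missing = 0.1,
                                  localities = NULL) {
  a1 <- matrix(sample(10:20, n * L, TRUE), n, L)
  a2 <- matrix(sample(10:20, n * L, TRUE), n, L)
  drop <- matrix(runif(n * L) < missing, n, L)
  a1[drop] <- NA; a2[drop] <- NA
  genotype_table(sprintf("ind%02d", seq_len(n)),
                 sprintf("loc%02d", seq_len(L)), a1, a2,
                 locality = localities)
}

# reference-table stub with Gaussian statistics, for engine-level oracles
# that need no coalescent simulation
fake_reference_table <- function(n_per, means, sd = 1, n_stats = 4,
                                 seed = 1) {
  set.seed(seed)
  scen <- names(means)
  stats <- do.call(rbind, lapply(scen, function(s)
    matrix(rnorm(n_per * n_stats, mean = means[[s]], sd = sd), n_per,
           n_stats)))
  colnames(stats) <- paste0("s", seq_len(n_stats))
  structure(list(scenario = factor(rep(scen, each = n_per), levels = scen),
                 stats = stats,
                 params = replicate(n_per * length(scen),
                                    c(theta = rnorm(1)), simplify = FALSE),
                 seeds = seq_len(n_per * length(scen)), design = NULL),
            class = "reference_table")
}

two_pop_set <- function(lo1, hi1, lo2, hi2, design = NULL,
                        names = c("S1", "S2")) {
  if (is.null(design))
    design <- sampling_design(c("A", "B"), c(8, 8), c(8, 8), n_loci = 4,
                              mt_length = 200)
  mk <- function(nm, lo, hi) scenario(nm,
    params = list(
      list(name = "N_A", dist = "unif", min = lo, max = hi, unit = "ind"),
      list(name = "N_B", dist = "unif", min = lo, max = hi, unit = "ind"),
      list(name = "N_anc", dist = "unif", min = lo, max = hi, unit = "ind"),
      list(name = "T1", dist = "unif", min = 500, max = 2000,
           unit = "years")),
    demes = c("A", "B", "ANC"),
    sizes = list(A = list(list(time = "0", size = "N_A")),
                 B = list(list(time = "0", size = "N_B")),
                 ANC = list(list(time = "0", size = "N_anc"))),
    events = list(
      list(time = "T1", type = "merge", from = "A", to = "ANC"),
      list(time = "T1", type = "merge", from = "B", to = "ANC")))
  scenario_set(list(mk(names[1], lo1, hi1), mk(names[2], lo2, hi2)),
               design)
}
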