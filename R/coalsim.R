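#' Multi-population demographic model
#'
#' A backward-time demography: a set of demes with piecewise-constant
#' diploid effective sizes and a list of merge/admixture events joining
#' lineage pools as time recedes. Every sampled deme must reach a single
#' root deme. Times are in generations before present; sizes in diploid
#' individuals.
#'
#' @param demes Character vector of deme names.
#' @param sizes Named list (one entry per deme) of data frames with columns
#'   `time` (generations, ascending, starting at 0) and `size` (diploid
#'   individuals); each size applies from its `time` backwards until the
#'   next change.
#' @param events `NULL` or a data frame with columns `time`, `type`
#'   (`"merge"` or `"admix"`), `from`, `to`, and for admixture `to2` and
#'   `prob` (probability that a lineage moves to `to`; the remainder moves
#'   to `to2`).
#' @param gen_time Generation time in years (used when converting priors
#'   specified in years; default 10).
#' @return An object of class `demography`.
#' @export
demography <- function(demes, sizes, events = NULL, gen_time = 10) {
  obj <- structure(list(demes = as.character(demes), sizes = sizes,
                        events = events, gen_time = gen_time),
                   class = "demography")
  validate_demography(obj)
  obj
}

#' Validate a demography
#'
#' Checks size specifications (positive sizes, ordered change times
#' starting at 0), event well-formedness, and that the deme-merge graph
#' leaves exactly one root deme so no lineage can be stranded.
#'
#' @param dem A [demography()].
#' @return `dem`, invisibly; errors describe the first violation found.
#' @export
validate_demography <- function(dem) {
  if (!setequal(names(dem$sizes), dem$demes))
    stop("sizes must name every deme exactly once")
  for (d in dem$demes) {
    s <- dem$sizes[[d]]
    if (!all(c("time", "size") %in% names(s)))
      stop("size table for ", d, " needs 'time' and 'size'")
    if (s$time[1] != 0 || is.unsorted(s$time, strictly = TRUE))
      stop("size change times for ", d,
           " must start at 0 and increase strictly")
    if (any(s$size <= 0)) stop("non-positive size in deme ", d)
  }
  ev <- dem$events
  if (!is.null(ev) && nrow(ev)) {
    if (any(ev$time <= 0)) stop("event times must be strictly positive")
    if (!all(ev$type %in% c("merge", "admix")))
      stop("event type must be 'merge' or 'admix'")
    if (!all(c(ev$from, ev$to) %in% dem$demes))
      stop("event references unknown deme")
    ev <- ev[order(ev$time), , drop = FALSE]
    terminated <- character(0)
    for (k in seq_len(nrow(ev))) {
      if (ev$from[k] %in% terminated)
        stop("deme ", ev$from[k], " receives an event after it was emptied")
      targets <- c(ev$to[k],
                   if (ev$type[k] == "admix") ev$to2[k])
      if (any(targets %in% terminated))
        stop("event at time ", ev$time[k], " targets an emptied deme")
      if (ev$type[k] == "admix") {
        if (is.na(ev$prob[k]) || ev$prob[k] < 0 || ev$prob[k] > 1)
          stop("admixture probability must be in [0, 1]")
        if (!(ev$to2[k] %in% dem$demes))
          stop("event references unknown deme")
      }
      terminated <- c(terminated, ev$from[k])
    }
    open <- setdiff(dem$demes, terminated)
    if (length(open) != 1)
      stop("demography validation error: ", length(open),
           " root demes remain (", paste(open, collapse = ", "),
           "); lineages would be stranded")
  } else if (length(dem$demes) != 1) {
    stop("demography validation error: multiple demes but no merge events")
  }
  invisible(dem)
}

#' Single-deme constant-size demography
#' @param n_diploid Diploid effective size.
#' @param deme Deme name.
#' @param gen_time Generation time in years.
#' @return A [demography()].
#' @export
constant_demography <- function(n_diploid, deme = "pop1", gen_time = 10) {
  demography(deme,
             setNames(list(data.frame(time = 0, size = n_diploid)), deme),
             gen_time = gen_time)
}

#' Microsatellite and sequence mutation model
#'
#' @param mu_mic Microsatellite mutation rate per locus per generation.
#' @param p_gsm Geometric parameter of the generalized stepwise model in
#'   `[0, 1)`; 0 gives the strict single-step model.
#' @param range Number of contiguous allele states (reflecting boundaries).
#' @param mu_mt mtDNA mutation rate per site per generation.
#' @param kappa Transition/transversion ratio for sequence mutation.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu_mic = 5e-4, p_gsm = 0.15, range = 40,
                           mu_mt = 1e-7, kappa = 10) {
  stopifnot(mu_mic >= 0, mu_mt >= 0, p_gsm >= 0, p_gsm < 1, range >= 2,
            kappa > 0)
  structure(list(mu_mic = mu_mic, p_gsm = p_gsm, range = as.integer(range),
                 mu_mt = mu_mt, kappa = kappa), class = "mutation_model")
}

#' Sample a coalescent genealogy
#'
#' Standard continuous-time coalescent on the demography: within a deme of
#' diploid size N, a pair of nuclear gene copies coalesces at rate 1/(2N)
#' per generation; mtDNA copies (haploid, maternally inherited, effective
#' copy number N/2) at rate 2/N. Lineages change demes only at merge or
#' admixture events.
#'
#' @param dem A [demography()].
#' @param samples Named integer vector: number of sampled gene copies per
#'   deme (demes omitted or 0 are unsampled).
#' @param marker `"nuclear"` or `"mtDNA"` (sets the copy-number scaling).
#' @return A `genealogy`: list with `parent` (1-based parent index, 0 for
#'   the root), `time` (node times in generations; tips first), `n_tip`,
#'   and `tip_deme`.
#' @export
sample_genealogy <- function(dem, samples, marker = c("nuclear", "mtDNA")) {
  marker <- match.arg(marker)
  scale <- if (marker == "nuclear") 2 else 0.5
  samp <- setNames(rep(0L, length(dem$demes)), dem$demes)
  if (is.null(names(samples)))
    stop("samples must be a named vector of gene-copy counts")
  if (!all(names(samples) %in% dem$demes))
    stop("samples name unknown demes")
  samp[names(samples)] <- as.integer(samples)
  size_times <- lapply(dem$demes, function(d) dem$sizes[[d]]$time)
  size_vals <- lapply(dem$demes, function(d) dem$sizes[[d]]$size * scale)
  ev <- dem$events
  if (is.null(ev) || !nrow(ev)) {
    ev <- data.frame(time = numeric(0), type = character(0),
                     from = character(0), to = character(0),
                     to2 = character(0), prob = numeric(0))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  if (!("to2" %in% names(ev))) ev$to2 <- NA_character_
  if (!("prob" %in% names(ev))) ev$prob <- NA_real_
  to2 <- match(ev$to2, dem$demes)
  to2[is.na(to2)] <- 1L
  res <- sample_genealogy_cpp(
    samp, size_times, size_vals, ev$time,
    as.integer(ev$type == "admix"), match(ev$from, dem$demes),
    match(ev$to, dem$demes), to2,
    ifelse(is.na(ev$prob), 0.5, ev$prob))
  structure(list(parent = res$parent + 1L, time = res$time,
                 n_tip = res$n_tip,
                 tip_deme = rep(dem$demes, samp)),
            class = "genealogy")
}

#' Total branch length of a genealogy (generations)
#' @param gen A genealogy from [sample_genealogy()].
#' @return Sum of branch lengths in generations.
#' @export
total_branch_length <- function(gen) {
  has_parent <- gen$parent > 0
  sum(gen$time[gen$parent[has_parent]] - gen$time[has_parent])
}

#' Time to the most recent common ancestor (generations)
#' @param gen A genealogy from [sample_genealogy()].
#' @return TMRCA in generations (0 for a single lineage).
#' @export
tmrca <- function(gen) max(gen$time)

#' Drop microsatellite mutations on a genealogy
#'
#' Poisson mutations along branches at the per-locus rate; each mutation
#' steps the allele by `k` repeat units with `k - 1 ~ Geometric(1 - p_gsm)`
#' and random sign, reflected at the boundaries of the contiguous state
#' space. The root allele sits at mid-range (all statistics used downstream
#' are translation invariant).
#'
#' @param gen A genealogy from [sample_genealogy()].
#' @param model A [mutation_model()].
#' @return Integer vector of tip allele states in `[0, range - 1]`.
#' @export
mutate_microsat <- function(gen, model) {
  mutate_microsat_cpp(gen$parent - 1L, gen$time, gen$n_tip, model$mu_mic,
                      model$p_gsm, model$range)
}

#' Drop finite-sites sequence mutations on a genealogy
#'
#' Per-site Poisson mutations with transition:transversion weighting
#' `kappa:1`; the root sequence is uniform random. Only sites hit by at
#' least one mutation are returned explicitly.
#'
#' @param gen A genealogy from [sample_genealogy()].
#' @param model A [mutation_model()].
#' @param length Number of sites.
#' @return List with `positions` (1-based mutated sites), `tips` (tips x
#'   sites integer matrix, 0=A,1=C,2=G,3=T) and `root_base`.
#' @export
mutate_sequence <- function(gen, model, length) {
  mutate_sequence_cpp(gen$parent - 1L, gen$time, gen$n_tip, model$mu_mt,
                      as.integer(length), model$kappa)
}

#' Sampling design of a two-marker study
#'
#' @param pops Population (deme) names that are sampled.
#' @param n_diploid Integer vector: diploid individuals genotyped per
#'   population.
#' @param n_mt Integer vector: mtDNA sequences per population (at most
#'   `n_diploid`).
#' @param n_loci Number of microsatellite loci.
#' @param mt_length mtDNA alignment length in sites.
#' @param allele_range Contiguous microsatellite allele states.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(pops, n_diploid, n_mt, n_loci = 11,
                            mt_length = 597, allele_range = 40) {
  stopifnot(length(pops) == length(n_diploid),
            length(pops) == length(n_mt),
            all(n_diploid >= 0), all(n_mt >= 0), all(n_mt <= n_diploid),
            n_loci >= 0, mt_length >= 1)
  if (sum(n_diploid) + sum(n_mt) == 0 || (n_loci == 0 && sum(n_mt) == 0))
    stop("at least one marker must be sampled")
  structure(list(pops = as.character(pops),
                 n_diploid = as.integer(n_diploid),
                 n_mt = as.integer(n_mt), n_loci = as.integer(n_loci),
                 mt_length = as.integer(mt_length),
                 allele_range = as.integer(allele_range)),
            class = "sampling_design")
}

.ALLELE_OFFSET <- 10L  # repeat-unit offset keeping reported sizes positive
.BASES <- c("A", "C", "G", "T")

# fast path: raw matrices, no container overhead (used for ABC reference
# tables where millions of datasets may be simulated)
.sim_raw <- function(dem, model, design) {
  nuc_samples <- setNames(2L * design$n_diploid, design$pops)
  n_ind <- sum(design$n_diploid)
  a1 <- a2 <- matrix(NA_integer_, n_ind, design$n_loci)
  if (design$n_loci > 0 && n_ind > 0) {
    for (l in seq_len(design$n_loci)) {
      gen <- sample_genealogy(dem, nuc_samples, "nuclear")
      st <- mutate_microsat(gen, model)
      a1[, l] <- st[seq(1, length(st), by = 2)]
      a2[, l] <- st[seq(2, length(st), by = 2)]
    }
  }
  pop <- factor(rep(design$pops, design$n_diploid), levels = design$pops)
  mt <- NULL
  if (sum(design$n_mt) > 0) {
    gen_mt <- sample_genealogy(dem, setNames(design$n_mt, design$pops),
                               "mtDNA")
    seqres <- mutate_sequence(gen_mt, model, design$mt_length)
    mt <- list(positions = seqres$positions, tips = seqres$tips,
               root_base = seqres$root_base, length = design$mt_length,
               pop = factor(rep(design$pops, design$n_mt),
                            levels = design$pops))
  }
  list(a1 = a1, a2 = a2, pop = pop, mt = mt)
}

#' Simulate a two-marker dataset under a demographic draw
#'
#' Independent genealogies per microsatellite locus plus one mtDNA
#' genealogy, mutated and packaged in the same containers the observed data
#' use, so simulated data flow through every statistic unchanged.
#' Bit-identical under a fixed seed.
#'
#' @param draw A list with elements `demography` (a [demography()]) and
#'   `mutation` (a [mutation_model()]), e.g. from [sample_prior()].
#' @param design A [sampling_design()].
#' @param seed Optional integer seed.
#' @return List with `genotypes` ([genotype_table()]), `haplotypes`
#'   ([haplotype_alignment()] or `NULL`), `partition`.
#' @export
simulate_dataset <- function(draw, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- draw$mutation
  model$range <- design$allele_range
  raw <- .sim_raw(draw$demography, model, design)
  ids <- unlist(lapply(seq_along(design$pops), function(k)
    sprintf("%s_%03d", design$pops[k], seq_len(design$n_diploid[k]))))
  gt <- genotype_table(ids, sprintf("locus%02d", seq_len(design$n_loci)),
                       raw$a1 + .ALLELE_OFFSET, raw$a2 + .ALLELE_OFFSET,
                       locality = as.character(raw$pop))
  mt_obj <- NULL
  mt_ids <- character(0)
  if (!is.null(raw$mt)) {
    consensus <- sample(.BASES, design$mt_length, replace = TRUE)
    consensus[raw$mt$positions] <- .BASES[raw$mt$root_base + 1L]
    seqs <- vapply(seq_len(nrow(raw$mt$tips)), function(i) {
      s <- consensus
      s[raw$mt$positions] <- .BASES[raw$mt$tips[i, ] + 1L]
      paste(s, collapse = "")
    }, character(1))
    # mtDNA individuals are the first n_mt of each population
    mt_ids <- unlist(lapply(seq_along(design$pops), function(k)
      sprintf("%s_%03d", design$pops[k], seq_len(design$n_mt[k]))))
    mt_obj <- haplotype_alignment(mt_ids, seqs)
  }
  part <- partition(ids, as.character(raw$pop))
  list(genotypes = gt, haplotypes = mt_obj, partition = part)
}

#' Coalescent null test for the Garza-Williamson M-ratio
#'
#' Simulates the mean M-ratio under a constant-size single-population
#' scenario with priors on the effective size and the generalized stepwise
#' mutation parameters, matching the observed sample size and locus count.
#' The p-value is the proportion of simulated mean M values below the
#' observed one.
#'
#' @param observed_m Observed mean M-ratio for the population.
#' @param n_ind Number of diploid individuals in the population.
#' @param n_loci Number of microsatellite loci.
#' @param n_sims Number of simulations (>= 100; the study-scale default is
#'   configurable downward for interactive use).
#' @param seed Optional integer seed.
#' @param ne_bounds Uniform prior bounds on the diploid effective size.
#' @param mu_bounds Log-uniform prior bounds on the microsatellite rate.
#' @param p_gsm_bounds Uniform prior bounds on the GSM parameter.
#' @param allele_range Allele-range bound (contiguous states).
#' @return List with `p_value`, `observed_m` and the simulated `null_m`.
#' @export
m_gw_test <- function(observed_m, n_ind, n_loci, n_sims = 10000,
                      seed = NULL, ne_bounds = c(10, 20000),
                      mu_bounds = c(1e-4, 1e-3), p_gsm_bounds = c(0, 0.3),
                      allele_range = 40) {
  if (n_sims < 100)
    stop("n_sims < 100 gives an unstable p-value; refuse")
  if (!is.null(seed)) set.seed(seed)
  null_m <- vapply(seq_len(n_sims), function(i) {
    ne <- runif(1, ne_bounds[1], ne_bounds[2])
    mu <- exp(runif(1, log(mu_bounds[1]), log(mu_bounds[2])))
    pg <- runif(1, p_gsm_bounds[1], p_gsm_bounds[2])
    dem <- constant_demography(ne)
    model <- mutation_model(mu_mic = mu, p_gsm = pg, range = allele_range)
    mean(vapply(seq_len(n_loci), function(l) {
      gen <- sample_genealogy(dem, c(pop1 = 2L * n_ind), "nuclear")
      st <- mutate_microsat(gen, model)
      length(unique(st)) / (diff(range(st)) + 1)
    }, numeric(1)))
  }, numeric(1))
  list(p_value = mean(null_m < observed_m), observed_m = observed_m,
       null_m = null_m)
}
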