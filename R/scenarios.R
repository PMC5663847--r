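#' @name scenario-dsl
#' @title Declarative demographic scenarios with priors
#' @description Scenarios are declarative templates: parameter declarations
#'   (uniform or log-uniform priors, units of years or diploid
#'   individuals), size and event templates whose entries are expressions
#'   over the parameters (times in years), and inequality conditions
#'   enforced by rejection resampling. Realizing a draw converts years to
#'   generations and yields a validated [demography()]. The whole
#'   representation is plain data, so scenario sets serialize losslessly to
#'   YAML.
NULL

.prior_spec <- function(name, dist, min, max, unit = "") {
  stopifnot(dist %in% c("unif", "logunif", "fixed"), min <= max)
  list(name = name, dist = dist, min = min, max = max, unit = unit)
}

#' Declare a demographic scenario
#'
#' @param name Scenario name (unique within a set).
#' @param params List of prior declarations, each
#'   `list(name, dist = "unif"|"logunif"|"fixed", min, max, unit)`.
#' @param demes Character vector of deme names (sampled and ancestral).
#' @param sizes Named list per deme; each entry a list of
#'   `list(time = <expr>, size = <expr>)` pieces with times in years and
#'   sizes in diploid individuals; expressions are strings over parameter
#'   names.
#' @param events List of `list(time, type, from, to, to2, prob)` templates
#'   (times in years; `prob` an expression for admixture).
#' @param conditions Character vector of logical expressions over the
#'   parameters that every accepted draw must satisfy.
#' @param description Free-text description.
#' @return An object of class `demographic_scenario`.
#' @export
scenario <- function(name, params, demes, sizes, events,
                     conditions = character(0), description = "") {
  declared <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(declared)) stop("duplicate parameter names")
  structure(list(name = name, params = params, demes = demes,
                 sizes = sizes, events = events, conditions = conditions,
                 description = description),
            class = "demographic_scenario")
}

.draw_prior_value <- function(p) {
  switch(p$dist,
         unif = runif(1, p$min, p$max),
         logunif = exp(runif(1, log(p$min), log(p$max))),
         fixed = p$min)
}

.eval_expr <- function(expr, env) {
  v <- eval(parse(text = expr), envir = env)
  if (!is.finite(v)) stop("template expression '", expr,
                          "' is not finite")
  v
}

#' Realize a scenario at fixed parameter values
#'
#' Evaluates the size and event templates at the supplied parameter values,
#' converts times from years to generations, and returns a validated
#' [demography()].
#'
#' @param sc A [scenario()].
#' @param par Named numeric vector/list of parameter values.
#' @param gen_time Generation time in years.
#' @return A [demography()].
#' @export
realize_scenario <- function(sc, par, gen_time = 10) {
  env <- list2env(as.list(par))
  sizes <- lapply(sc$sizes, function(pieces) {
    tm <- vapply(pieces, function(p)
      .eval_expr(as.character(p$time), env), numeric(1)) / gen_time
    sz <- vapply(pieces, function(p)
      .eval_expr(as.character(p$size), env), numeric(1))
    o <- order(tm)
    data.frame(time = tm[o], size = sz[o])
  })
  names(sizes) <- names(sc$sizes)
  events <- NULL
  if (length(sc$events)) {
    events <- data.frame(
      time = vapply(sc$events, function(e)
        .eval_expr(as.character(e$time), env), numeric(1)) / gen_time,
      type = vapply(sc$events, `[[`, character(1), "type"),
      from = vapply(sc$events, `[[`, character(1), "from"),
      to = vapply(sc$events, `[[`, character(1), "to"),
      to2 = vapply(sc$events, function(e) e$to2 %||% NA_character_,
                   character(1)),
      prob = vapply(sc$events, function(e)
        if (is.null(e$prob)) NA_real_ else
          .eval_expr(as.character(e$prob), env), numeric(1)),
      stringsAsFactors = FALSE)
  }
  demography(sc$demes, sizes, events, gen_time = gen_time)
}

#' A set of competing scenarios sharing one design
#'
#' @param scenarios List of [scenario()] objects (unique names).
#' @param design A [sampling_design()] shared by all scenarios.
#' @param mut_prior Mutation-model priors: list with elements `mu_mic`
#'   (log-uniform bounds), `p_gsm` (uniform bounds), `mu_mt` (log-uniform
#'   bounds), `kappa` (uniform bounds).
#' @param gen_time Generation time in years.
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(scenarios, design,
                         mut_prior = default_mutation_prior(),
                         gen_time = 10) {
  nms <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("scenario names must be unique")
  structure(list(scenarios = setNames(scenarios, nms), design = design,
                 mut_prior = mut_prior, gen_time = gen_time),
            class = "scenario_set")
}

#' Default mutation priors
#'
#' Generalized stepwise microsatellite mutation with log-uniform per-locus
#' rate in `[1e-4, 1e-3]` and uniform geometric parameter in `[0, 0.3]`;
#' sequence mutation with log-uniform per-site rate in `[1e-8, 1e-6]` and
#' uniform transition/transversion ratio in `[5, 20]`.
#' @return A list of prior bounds.
#' @export
default_mutation_prior <- function() {
  list(mu_mic = c(1e-4, 1e-3), p_gsm = c(0, 0.3),
       mu_mt = c(1e-8, 1e-6), kappa = c(5, 20))
}

.draw_mutation <- function(mut_prior, allele_range) {
  mutation_model(
    mu_mic = exp(runif(1, log(mut_prior$mu_mic[1]),
                       log(mut_prior$mu_mic[2]))),
    p_gsm = runif(1, mut_prior$p_gsm[1], mut_prior$p_gsm[2]),
    range = allele_range,
    mu_mt = exp(runif(1, log(mut_prior$mu_mt[1]), log(mut_prior$mu_mt[2]))),
    kappa = runif(1, mut_prior$kappa[1], mut_prior$kappa[2]))
}

#' Draw a scenario realization from its priors
#'
#' Parameters are drawn independently from their priors and the draw is
#' rejected until every scenario condition holds; mutation parameters come
#' from the set-level priors. The realized demography is validated.
#'
#' @param set A [scenario_set()].
#' @param name Scenario name within the set.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-resampling cap before declaring the prior
#'   specification unsatisfiable.
#' @return A list `scenario`, `params` (named, including mutation
#'   parameters), `demography`, `mutation`.
#' @export
sample_prior <- function(set, name, seed = NULL, max_tries = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  sc <- set$scenarios[[name]]
  if (is.null(sc)) stop("unknown scenario: ", name)
  for (try in seq_len(max_tries)) {
    par <- vapply(sc$params, .draw_prior_value, numeric(1))
    names(par) <- vapply(sc$params, `[[`, character(1), "name")
    env <- list2env(as.list(par))
    ok <- all(vapply(sc$conditions, function(cn)
      isTRUE(eval(parse(text = cn), envir = env)), logical(1)))
    if (ok) {
      model <- .draw_mutation(set$mut_prior, set$design$allele_range)
      dem <- realize_scenario(sc, par, set$gen_time)
      mutp <- c(mu_mic = model$mu_mic, p_gsm = model$p_gsm,
                mu_mt = model$mu_mt, kappa = model$kappa)
      return(list(scenario = name, params = c(par, mutp),
                  demography = dem, mutation = model))
    }
  }
  stop("prior specification error: conditions for scenario ", name,
       " unsatisfiable within ", max_tries, " attempts")
}

# ---- shipped scenario sets ------------------------------------------------

.default_design <- function() {
  sampling_design(pops = c("XCSS", "PY", "TL"),
                  n_diploid = c(16, 58, 17), n_mt = c(16, 56, 17),
                  n_loci = 11, mt_length = 597)
}

.size_prior <- function(name) .prior_spec(name, "unif", 10, 20000,
                                          "diploid individuals")

.const_sizes <- function(demes, size_params) {
  out <- lapply(size_params, function(s)
    list(list(time = "0", size = s)))
  names(out) <- demes
  out
}

#' Step-1 scenario set: population branching order
#'
#' Ten scenarios over the three focal populations: the trichotomy
#' (simultaneous three-way split), the three rooted bifurcating orders, and
#' six admixture variants (each population in turn formed by admixture
#' between the two others, with either of the two as the major parent and
#' the minor contribution drawn uniform on `[0, 0.5]`). Constant sizes
#' within branches.
#'
#' @param design A [sampling_design()] over three populations (default:
#'   the study design, XCSS/PY/TL).
#' @return A [scenario_set()] of 10 scenarios named SC1..SC10, SC1 the
#'   trichotomy.
#' @export
build_step1_topologies <- function(design = .default_design()) {
  pops <- design$pops
  stopifnot(length(pops) == 3)
  np <- paste0("N_", pops)
  base_params <- c(lapply(np, .size_prior), list(.size_prior("N_anc")))
  t1 <- .prior_spec("T1", "unif", 100, 5000, "years")
  t2 <- .prior_spec("T2", "unif", 100, 5000, "years")
  scn <- list()

  scn$SC1 <- scenario(
    "SC1", c(base_params, list(t1)),
    demes = c(pops, "ANC"),
    sizes = .const_sizes(c(pops, "ANC"), c(np, "N_anc")),
    events = lapply(pops, function(p)
      list(time = "T1", type = "merge", from = p, to = "ANC")),
    description = paste("trichotomy:", paste(pops, collapse = ", "),
                        "diverge simultaneously"))

  bifurc <- function(nm, sis1, sis2, out) {
    scenario(
      nm, c(base_params, list(.size_prior("N_anc1"), t1, t2)),
      demes = c(pops, "ANC1", "ANC"),
      sizes = .const_sizes(c(pops, "ANC1", "ANC"),
                           c(np, "N_anc1", "N_anc")),
      events = list(
        list(time = "T1", type = "merge", from = sis1, to = "ANC1"),
        list(time = "T1", type = "merge", from = sis2, to = "ANC1"),
        list(time = "T2", type = "merge", from = "ANC1", to = "ANC"),
        list(time = "T2", type = "merge", from = out, to = "ANC")),
      conditions = "T2 > T1",
      description = sprintf("((%s,%s),%s)", sis1, sis2, out))
  }
  scn$SC2 <- bifurc("SC2", pops[1], pops[2], pops[3])
  scn$SC3 <- bifurc("SC3", pops[1], pops[3], pops[2])
  scn$SC4 <- bifurc("SC4", pops[2], pops[3], pops[1])

  admix <- function(nm, hybrid, major, minor) {
    scenario(
      nm, c(base_params,
            list(.prior_spec("T_adm", "unif", 100, 5000, "years"), t2,
                 .prior_spec("r_adm", "unif", 0, 0.5, "proportion"))),
      demes = c(pops, "ANC"),
      sizes = .const_sizes(c(pops, "ANC"), c(np, "N_anc")),
      events = list(
        list(time = "T_adm", type = "admix", from = hybrid, to = major,
             to2 = minor, prob = "1 - r_adm"),
        list(time = "T2", type = "merge", from = major, to = "ANC"),
        list(time = "T2", type = "merge", from = minor, to = "ANC")),
      conditions = "T2 > T_adm",
      description = sprintf(
        "%s admixed, major parent %s, minor %s (rate r_adm)",
        hybrid, major, minor))
  }
  k <- 5
  for (h in seq_along(pops)) {
    others <- pops[-h]
    for (m in 1:2) {
      scn[[paste0("SC", k)]] <-
        admix(paste0("SC", k), pops[h], others[m], others[3 - m])
      k <- k + 1
    }
  }
  scenario_set(unname(scn), design)
}

#' Step-2 scenario set: size changes during divergence
#'
#' Six nested scenarios on the trichotomy: SC1 constant sizes; SC2 decline
#' in the daughter populations; SC3 ancestral founder bottleneck (large
#' ancestral size, brief small founder phase, expansion, then split); SC4
#' expansion in the daughters; SC5 simple ancestral decline; SC6 simple
#' ancestral expansion. SC1 is recovered from SC3 by equating the three
#' ancestral sizes, from SC2/SC4 by equating pre- and post-change daughter
#' sizes, and from SC5/SC6 by equating the two ancestral sizes.
#'
#' @inheritParams build_step1_topologies
#' @return A [scenario_set()] of 6 scenarios named SC1..SC6.
#' @export
build_step2_sizechange <- function(design = .default_design()) {
  pops <- design$pops
  stopifnot(length(pops) == 3)
  np <- paste0("N_", pops)
  dparams <- lapply(np, .size_prior)
  t_isol <- .prior_spec("T_isol2", "unif", 100, 5000, "years")
  t_exp <- .prior_spec("T_exp2", "unif", 1000, 50000, "years")
  merge_all <- lapply(pops, function(p)
    list(time = "T_isol2", type = "merge", from = p, to = "ANC"))
  scn <- list()

  scn$SC1 <- scenario(
    "SC1", c(dparams, list(.size_prior("N_exp2"), t_isol)),
    demes = c(pops, "ANC"),
    sizes = .const_sizes(c(pops, "ANC"), c(np, "N_exp2")),
    events = merge_all,
    description = "constant sizes since the split")

  scn$SC2 <- scenario(
    "SC2", c(dparams, list(.size_prior("N_exp2"), .size_prior("N_pre"),
                           t_isol,
                           .prior_spec("T_chg", "unif", 10, 5000, "years"))),
    demes = c(pops, "ANC"),
    sizes = c(setNames(lapply(np, function(s) list(
      list(time = "0", size = s),
      list(time = "T_chg", size = "N_pre"))), pops),
      list(ANC = list(list(time = "0", size = "N_exp2")))),
    events = merge_all,
    conditions = c("T_chg < T_isol2", paste("N_pre >", np)),
    description = "decline in the daughter populations after the split")

  scn$SC3 <- scenario(
    "SC3", c(dparams, list(.size_prior("N_exp2"), .size_prior("N_anc2"),
                           .prior_spec("N_founder", "unif", 2, 500,
                                       "diploid individuals"),
                           t_isol, t_exp,
                           .prior_spec("DB", "unif", 10, 500, "years"))),
    demes = c(pops, "ANC"),
    sizes = c(.const_sizes(pops, np),
              list(ANC = list(
                list(time = "0", size = "N_exp2"),
                list(time = "T_exp2", size = "N_founder"),
                list(time = "T_exp2 + DB", size = "N_anc2")))),
    events = merge_all,
    conditions = "T_exp2 > T_isol2",
    description = paste("ancestral founder bottleneck: few founders",
                        "colonize at T_exp2 and expand to N_exp2 before",
                        "the split"))

  scn$SC4 <- scenario(
    "SC4", c(dparams, list(.size_prior("N_exp2"), .size_prior("N_pre"),
                           t_isol,
                           .prior_spec("T_chg", "unif", 10, 5000, "years"))),
    demes = c(pops, "ANC"),
    sizes = c(setNames(lapply(np, function(s) list(
      list(time = "0", size = s),
      list(time = "T_chg", size = "N_pre"))), pops),
      list(ANC = list(list(time = "0", size = "N_exp2")))),
    events = merge_all,
    conditions = c("T_chg < T_isol2", paste("N_pre <", np)),
    description = "expansion in the daughter populations after the split")

  anc_change <- function(nm, cond, desc) {
    scenario(
      nm, c(dparams, list(.size_prior("N_exp2"), .size_prior("N_anc2"),
                          t_isol, t_exp)),
      demes = c(pops, "ANC"),
      sizes = c(.const_sizes(pops, np),
                list(ANC = list(list(time = "0", size = "N_exp2"),
                                list(time = "T_exp2", size = "N_anc2")))),
      events = merge_all,
      conditions = c("T_exp2 > T_isol2", cond),
      description = desc)
  }
  scn$SC5 <- anc_change("SC5", "N_anc2 > N_exp2",
                        "simple ancestral decline before the split")
  scn$SC6 <- anc_change("SC6", "N_anc2 < N_exp2",
                        "simple ancestral expansion before the split")
  scenario_set(unname(scn), design)
}

#' Step-3 scenario set: recent demographic collapse
#'
#' Two scenarios extending the step-2 winner (default: the ancestral
#' founder-bottleneck scenario): SC1 keeps sizes constant since the split;
#' SC2 adds an independent collapse in each daughter population within the
#' last `collapse_years` years (5 generations at the default generation
#' time), with per-population remnant fractions log-uniform on
#' `[0.001, 1]`.
#'
#' @inheritParams build_step1_topologies
#' @param base One of the scenarios of [build_step2_sizechange()] to
#'   extend; default `"SC3"`.
#' @param collapse_years Upper bound on the collapse time (years; default
#'   50, i.e. 5 generations of 10 years).
#' @return A [scenario_set()] of 2 scenarios named SC1, SC2.
#' @export
build_step3_collapse <- function(design = .default_design(), base = "SC3",
                                 collapse_years = 50) {
  step2 <- build_step2_sizechange(design)
  b <- step2$scenarios[[base]]
  if (is.null(b)) stop("unknown step-2 base scenario: ", base)
  pops <- design$pops
  sc1 <- b
  sc1$name <- "SC1"
  sc1$description <- paste("no recent collapse;", b$description)
  # add, for each daughter, a collapse piece below T_col
  col_params <- c(list(.prior_spec("T_col", "unif", 1e-6, collapse_years,
                                   "years")),
                  lapply(pops, function(p)
                    .prior_spec(paste0("f_", p), "logunif", 0.001, 1,
                                "remnant fraction")))
  sizes2 <- b$sizes
  for (p in pops) {
    pre <- sizes2[[p]][[1]]$size
    sizes2[[p]] <- c(
      list(list(time = "0",
                size = paste0("pmax(1, f_", p, " * (", pre, "))")),
           list(time = "T_col", size = pre)),
      sizes2[[p]][-1])
  }
  sc2 <- scenario("SC2", c(b$params, col_params), b$demes, sizes2,
                  b$events, b$conditions,
                  description = paste("independent recent collapse in each",
                                      "population;", b$description))
  scenario_set(list(sc1, sc2), design, gen_time = step2$gen_time)
}

# ---- YAML serialization ---------------------------------------------------

.scenario_to_list <- function(sc) {
  list(name = sc$name, description = sc$description, params = sc$params,
       demes = as.list(sc$demes), sizes = sc$sizes, events = sc$events,
       conditions = as.list(sc$conditions))
}

.scenario_from_list <- function(x) {
  scenario(x$name,
           lapply(x$params, function(p)
             .prior_spec(p$name, p$dist, p$min, p$max, p$unit %||% "")),
           unlist(x$demes), x$sizes, x$events,
           conditions = as.character(unlist(x$conditions)),
           description = x$description %||% "")
}

#' Serialize a scenario set to YAML
#' @param set A [scenario_set()].
#' @param path Optional file path; when `NULL` the YAML string is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
scenario_set_to_yaml <- function(set, path = NULL) {
  x <- list(gen_time = set$gen_time,
            design = list(pops = as.list(set$design$pops),
                          n_diploid = as.list(set$design$n_diploid),
                          n_mt = as.list(set$design$n_mt),
                          n_loci = set$design$n_loci,
                          mt_length = set$design$mt_length,
                          allele_range = set$design$allele_range),
            mut_prior = set$mut_prior,
            scenarios = lapply(unname(set$scenarios), .scenario_to_list))
  s <- yaml::as.yaml(x)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a scenario set from YAML
#' @param path File path or a YAML string.
#' @return A [scenario_set()].
#' @export
scenario_set_from_yaml <- function(path) {
  x <- if (file.exists(path)) yaml::read_yaml(path) else
    yaml::yaml.load(path)
  design <- sampling_design(unlist(x$design$pops),
                            unlist(x$design$n_diploid),
                            unlist(x$design$n_mt), x$design$n_loci,
                            x$design$mt_length, x$design$allele_range)
  scenario_set(lapply(x$scenarios, .scenario_from_list), design,
               mut_prior = lapply(x$mut_prior, unlist),
               gen_time = x$gen_time)
}
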