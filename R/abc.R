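#' @name abc-engine
#' @title Nested ABC workflow: reference tables, rejection, model choice,
#'   calibration, estimation, goodness-of-fit
#' @description The five-step likelihood-free workflow: (1) simulate a
#'   reference table of pseudo-observed datasets (PODs) per scenario and
#'   summarize them; (2) choose the model from the PODs closest to the
#'   observed statistics, via multinomial logistic regression on linear
#'   discriminant axes and via a random-forest classifier; (3) calibrate
#'   type-I/type-II and prior error rates on held-out PODs; (4) estimate
#'   parameter posteriors by local-linear regression adjustment; (5) check
#'   goodness-of-fit by posterior predictive simulation.
NULL

#' Build a reference table of simulated summary statistics
#'
#' Simulates `n_per_scenario` prior draws per scenario, each row seeded
#' deterministically from `seed` and its row index, and summarizes every
#' dataset with [compute_ss()].
#'
#' @param set A [scenario_set()].
#' @param n_per_scenario Number of PODs per scenario.
#' @param seed Integer base seed.
#' @param scenarios Optional subset of scenario names to simulate.
#' @return An object of class `reference_table`: `scenario` (factor),
#'   `stats` (matrix), `params` (list of named vectors), `seeds`, `design`.
#' @export
build_reference_table <- function(set, n_per_scenario, seed = 1,
                                  scenarios = names(set$scenarios)) {
  design <- set$design
  rows_stats <- vector("list", length(scenarios) * n_per_scenario)
  rows_params <- vector("list", length(rows_stats))
  scen_lab <- character(length(rows_stats))
  seeds <- integer(length(rows_stats))
  r <- 0
  for (si in seq_along(scenarios)) {
    nm <- scenarios[si]
    for (i in seq_len(n_per_scenario)) {
      r <- r + 1
      seeds[r] <- as.integer((seed + (si - 1) * n_per_scenario + i) %%
                               .Machine$integer.max)
      set.seed(seeds[r])
      draw <- sample_prior(set, nm)
      raw <- .sim_raw(draw$demography, draw$mutation, design)
      rows_stats[[r]] <- .ss_from_raw(raw, design)
      rows_params[[r]] <- draw$params
      scen_lab[r] <- nm
    }
  }
  structure(list(scenario = factor(scen_lab, levels = scenarios),
                 stats = do.call(rbind, rows_stats),
                 params = rows_params, seeds = seeds, design = design),
            class = "reference_table")
}

#' Restrict a reference table to one scenario
#' @param table A `reference_table`.
#' @param scenario_name Scenario to keep.
#' @return A `reference_table` with only that scenario's rows.
#' @export
subset_reference_table <- function(table, scenario_name) {
  keep <- which(table$scenario == scenario_name)
  structure(list(scenario = factor(as.character(table$scenario[keep]),
                                   levels = scenario_name),
                 stats = table$stats[keep, , drop = FALSE],
                 params = table$params[keep], seeds = table$seeds[keep],
                 design = table$design), class = "reference_table")
}

#' Merge reference tables (same design and statistic order)
#' @param ... `reference_table` objects.
#' @return A combined `reference_table`.
#' @export
bind_reference_tables <- function(...) {
  tabs <- list(...)
  if (!all(vapply(tabs, function(t)
    identical(colnames(t$stats), colnames(tabs[[1]]$stats)), logical(1))))
    stop("configuration error: summary-statistic dimensions differ")
  structure(list(
    scenario = factor(unlist(lapply(tabs, function(t)
      as.character(t$scenario)))),
    stats = do.call(rbind, lapply(tabs, `[[`, "stats")),
    params = do.call(c, lapply(tabs, `[[`, "params")),
    seeds = unlist(lapply(tabs, `[[`, "seeds")),
    design = tabs[[1]]$design), class = "reference_table")
}

#' Rejection step: nearest PODs to the observed statistics
#'
#' Euclidean distance on summary statistics standardized by the reference
#' table's median absolute deviation (falling back to the SD when the MAD
#' is 0; zero-variance statistics are dropped with a warning). Ties are
#' broken by row index, so selection is deterministic.
#'
#' @param observed Named numeric vector from [observed_ss()] /
#'   [compute_ss()].
#' @param table A `reference_table` (or plain statistics matrix).
#' @param tolerance Fraction of rows to keep, in `(0, 1]`.
#' @return List with `index` (selected row indices, nearest first),
#'   `distance` (their distances) and `scale` (the per-statistic scale
#'   used).
#' @export
rejection_select <- function(observed, table, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  stats <- if (inherits(table, "reference_table")) table$stats else table
  if (!is.null(colnames(stats)) && !is.null(names(observed)))
    observed <- observed[colnames(stats)]
  scale <- apply(stats, 2, mad)
  sds <- apply(stats, 2, sd)
  fallback <- scale == 0 & sds > 0
  scale[fallback] <- sds[fallback]
  dead <- scale == 0
  if (any(dead))
    warning("dropping zero-variance statistics from the distance: ",
            paste(colnames(stats)[dead], collapse = ", "))
  use <- which(!dead)
  z <- sweep(stats[, use, drop = FALSE], 2, observed[use], "-")
  z <- sweep(z, 2, scale[use], "/")
  d <- sqrt(rowSums(z^2))
  n_keep <- ceiling(tolerance * nrow(stats))
  ord <- order(d)  # stable: ties broken by row index
  idx <- ord[seq_len(n_keep)]
  list(index = idx, distance = d[idx], scale = scale)
}

.drop_constant <- function(m) {
  keep <- apply(m, 2, function(v) var(v) > 0)
  m[, keep, drop = FALSE]
}

.lda_project <- function(train, labels, newdata) {
  # standardize so the discriminant analysis sees unit-scale variables,
  # and drop those with (near-)zero pooled within-group variance, which
  # would make it singular
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  scl[scl == 0] <- 1
  train <- sweep(sweep(train, 2, ctr, "-"), 2, scl, "/")
  newdata <- sweep(sweep(newdata, 2, ctr, "-"), 2, scl, "/")
  wsd <- vapply(seq_len(ncol(train)), function(j) {
    sqrt(mean(tapply(train[, j], labels, function(v)
      if (length(v) > 1) var(v) else 0)))
  }, numeric(1))
  keep <- which(is.finite(wsd) & wsd > 1e-3)
  if (!length(keep)) stop("no usable statistics for LDA")
  train <- as.data.frame(train[, keep, drop = FALSE])
  newdata <- as.data.frame(newdata[, keep, drop = FALSE])
  fit <- suppressWarnings(MASS::lda(train, grouping = labels))
  list(train = as.matrix(predict(fit, train)$x),
       new = as.matrix(predict(fit, newdata)$x))
}

# delta-method CI for multinomial-logistic class probabilities at one point
.multinom_prob_ci <- function(fit, newdata, level = 0.95) {
  p_hat <- predict(fit, newdata = newdata, type = "probs")
  classes <- fit$lev
  if (length(classes) == 2) p_hat <- c(1 - p_hat, p_hat)
  names(p_hat) <- classes
  th <- as.vector(t(coef(fit)))
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)))
    return(list(prob = p_hat, ci = cbind(low = rep(NA, length(p_hat)),
                                         high = rep(NA, length(p_hat)))))
  probs_of <- function(theta) {
    co <- matrix(theta, nrow = length(classes) - 1, byrow = TRUE)
    x <- c(1, as.numeric(newdata[1, ]))
    eta <- c(0, co %*% x)
    exp(eta) / sum(exp(eta))
  }
  h <- 1e-6
  G <- vapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + h
    (probs_of(tp) - probs_of(th)) / h
  }, numeric(length(classes)))
  se <- sqrt(pmax(0, diag(G %*% V %*% t(G))))
  zq <- qnorm(1 - (1 - level) / 2)
  list(prob = p_hat,
       ci = cbind(low = pmax(0, p_hat - zq * se),
                  high = pmin(1, p_hat + zq * se)))
}

#' Model choice by logistic regression on LDA axes
#'
#' Linear discriminant analysis of the selected PODs' statistics (classes =
#' scenarios) followed by multinomial logistic regression of the scenario
#' on the discriminant axes, evaluated at the observed point. Confidence
#' intervals come from the regression's asymptotic covariance via the
#' delta method.
#'
#' @param table A `reference_table`.
#' @param selected Result of [rejection_select()] (or an index vector).
#' @param observed Observed summary-statistic vector.
#' @return List with `prob` (posterior probability per scenario, summing
#'   to 1), `ci`, `best`, `method`.
#' @export
model_choice_logistic <- function(table, selected, observed) {
  idx <- if (is.list(selected)) selected$index else selected
  y <- droplevels(table$scenario[idx])
  all_scen <- levels(table$scenario)
  if (nlevels(y) < 2) {
    warning("only one scenario among selected PODs; probability 1 for it")
    prob <- setNames(as.numeric(all_scen == levels(y)), all_scen)
    return(list(prob = prob,
                ci = cbind(low = prob, high = prob), best = levels(y),
                method = "lda_logistic"))
  }
  absent <- setdiff(all_scen, levels(y))
  if (length(absent))
    warning("scenarios absent from selected PODs get probability 0: ",
            paste(absent, collapse = ", "))
  X <- .drop_constant(table$stats[idx, , drop = FALSE])
  pr <- .lda_project(X, y, matrix(observed[colnames(X)], 1,
                                  dimnames = list(NULL, colnames(X))))
  df <- data.frame(pr$train)
  df$.y <- y
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500)
  nd <- as.data.frame(pr$new)
  colnames(nd) <- colnames(pr$train)
  res <- .multinom_prob_ci(fit, nd)
  prob <- setNames(rep(0, length(all_scen)), all_scen)
  ci <- cbind(low = prob, high = prob)
  prob[names(res$prob)] <- res$prob
  ci[names(res$prob), ] <- res$ci
  prob <- prob / sum(prob)
  list(prob = prob, ci = ci, best = names(which.max(prob)),
       method = "lda_logistic")
}

#' Model choice by random forest
#'
#' Classification forest on the raw summary statistics augmented with the
#' LDA axes, trained on the full reference table. The predicted scenario is
#' the majority vote; the posterior probability of the chosen scenario is
#' estimated by a regression forest fitted to the out-of-bag success
#' indicator, evaluated at the observed point; the prior error rate is the
#' out-of-bag misclassification rate.
#'
#' @param table A `reference_table`.
#' @param observed Observed summary-statistic vector.
#' @param n_trees Number of trees (>= 50 enforced).
#' @param seed Optional integer seed.
#' @return List with `best`, `votes` (per scenario), `post_prob`,
#'   `post_prob_sd`, `prior_error`, `method`.
#' @export
model_choice_rf <- function(table, observed, n_trees = 500, seed = NULL) {
  if (n_trees < 50) stop("n_trees < 50 gives unstable votes; refuse")
  if (!is.null(seed)) set.seed(seed)
  y <- droplevels(table$scenario)
  X <- .drop_constant(table$stats)
  obs <- matrix(observed[colnames(X)], 1,
                dimnames = list(NULL, colnames(X)))
  feat <- X
  obs_feat <- obs
  if (nlevels(y) >= 2) {
    pr <- .lda_project(X, y, obs)
    feat <- cbind(X, pr$train)
    obs_feat <- cbind(obs, pr$new)
  }
  rf <- randomForest::randomForest(x = feat, y = y, ntree = n_trees)
  votes <- predict(rf, obs_feat, type = "vote")[1, ] * n_trees
  best <- names(which.max(votes))
  prior_error <- mean(rf$predicted != y)
  success <- as.numeric(rf$predicted == y)
  # the 0/1 response intentionally goes through a regression forest
  rf_reg <- suppressWarnings(
    randomForest::randomForest(x = feat, y = success, ntree = n_trees))
  pp <- predict(rf_reg, obs_feat, predict.all = TRUE)
  post <- min(1, max(0, pp$aggregate[1]))
  post_sd <- sd(pp$individual[1, ]) / sqrt(n_trees)
  list(best = best, votes = votes, post_prob = post,
       post_prob_sd = post_sd, prior_error = prior_error, method = "rf")
}

#' Error-rate calibration on held-out PODs
#'
#' Simulates fresh PODs per scenario (never part of the reference table),
#' analyses each exactly like an observed dataset, and reports the
#' confusion matrix (rows sum to 1), per-scenario type-I error (fraction of
#' a scenario's PODs not assigned to it), per-scenario type-II error
#' (fraction of other scenarios' PODs assigned to it), and the prior error
#' rate under equal scenario priors.
#'
#' @param set A [scenario_set()].
#' @param table A `reference_table` built from `set`.
#' @param n_pods_per_scenario Held-out PODs per scenario.
#' @param tolerance Rejection tolerance used for each POD analysis.
#' @param seed Integer seed (offset internally so PODs never reuse
#'   reference-table seeds).
#' @param method `"lda_logistic"` (each POD gets its own rejection and
#'   regression) or `"rf"` (one forest classifies all PODs).
#' @return List with `confusion`, `type1`, `type2`, `prior_error`,
#'   `n_pods_per_scenario`.
#' @export
calibrate_errors <- function(set, table, n_pods_per_scenario = 100,
                             tolerance = 0.01, seed = 1,
                             method = c("lda_logistic", "rf")) {
  method <- match.arg(method)
  scen <- levels(table$scenario)
  design <- set$design
  pods <- list(); truth <- character(0)
  r <- 0
  for (si in seq_along(scen)) {
    for (i in seq_len(n_pods_per_scenario)) {
      r <- r + 1
      set.seed(as.integer((seed + 1500450271 + (si - 1) *
                             n_pods_per_scenario + i) %%
                            .Machine$integer.max))
      draw <- sample_prior(set, scen[si])
      raw <- .sim_raw(draw$demography, draw$mutation, design)
      pods[[r]] <- .ss_from_raw(raw, design)
      truth[r] <- scen[si]
    }
  }
  pods <- do.call(rbind, pods)
  assigned <- character(nrow(pods))
  if (method == "rf") {
    y <- droplevels(table$scenario)
    X <- .drop_constant(table$stats)
    pr <- .lda_project(X, y, pods[, colnames(X), drop = FALSE])
    rf <- randomForest::randomForest(x = cbind(X, pr$train), y = y,
                                     ntree = 500)
    assigned <- as.character(predict(
      rf, cbind(pods[, colnames(X), drop = FALSE], pr$new)))
  } else {
    for (k in seq_len(nrow(pods))) {
      sel <- suppressWarnings(rejection_select(pods[k, ], table, tolerance))
      mc <- suppressWarnings(model_choice_logistic(table, sel, pods[k, ]))
      assigned[k] <- mc$best
    }
  }
  conf <- table(factor(truth, levels = scen),
                factor(assigned, levels = scen))
  conf <- conf / rowSums(conf)
  type1 <- 1 - diag(conf)
  type2 <- vapply(seq_along(scen), function(s)
    mean(conf[-s, s]), numeric(1))
  names(type2) <- scen
  list(confusion = conf, type1 = type1, type2 = type2,
       prior_error = 1 - mean(diag(conf)),
       n_pods_per_scenario = n_pods_per_scenario, method = method)
}

.param_bounds <- function(set, scenario_name) {
  sc <- set$scenarios[[scenario_name]]
  b <- lapply(sc$params, function(p)
    c(min = p$min, max = p$max,
      log = as.numeric(identical(p$dist, "logunif"))))
  names(b) <- vapply(sc$params, `[[`, character(1), "name")
  mp <- set$mut_prior
  b$mu_mic <- c(min = mp$mu_mic[1], max = mp$mu_mic[2], log = 1)
  b$p_gsm <- c(min = mp$p_gsm[1], max = mp$p_gsm[2], log = 0)
  b$mu_mt <- c(min = mp$mu_mt[1], max = mp$mu_mt[2], log = 1)
  b$kappa <- c(min = mp$kappa[1], max = mp$kappa[2], log = 0)
  b
}

.to_unit <- function(x, b) {
  eps <- 1e-9
  u <- if (b["log"] > 0)
    (log(x) - log(b["min"])) / (log(b["max"]) - log(b["min"]))
  else (x - b["min"]) / (b["max"] - b["min"])
  pmin(1 - eps, pmax(eps, u))
}

.from_unit <- function(u, b) {
  u <- pmin(1, pmax(0, u))
  if (b["log"] > 0) exp(log(b["min"]) + u * (log(b["max"]) - log(b["min"])))
  else b["min"] + u * (b["max"] - b["min"])
}

#' Parameter estimation by local-linear regression adjustment
#'
#' Accepted parameter draws from the winning scenario are regressed on the
#' (standardized) deviation of their statistics from the observed vector
#' with Epanechnikov weights in the rejection distance; the regression
#' prediction at the observed point replaces the local mean. Bounded
#' parameters are adjusted on a logit-transformed unit scale (log scale
#' first for log-uniform priors) and back-transformed, so adjusted values
#' respect the prior bounds.
#'
#' @param set A [scenario_set()].
#' @param scenario_name The winning scenario.
#' @param table A `reference_table` containing that scenario's rows.
#' @param selected [rejection_select()] result computed on `table`.
#' @param observed Observed summary-statistic vector.
#' @param min_selected Minimum accepted rows (default 50); fewer is an
#'   error suggesting a wider tolerance.
#' @return An object of class `posterior_sample`: `adjusted` (matrix of
#'   adjusted draws), `raw` (unadjusted), `weights`, and `summary` (per
#'   parameter: mean, median, mode, 2.5%/97.5% quantiles).
#' @export
estimate_parameters <- function(set, scenario_name, table, selected,
                                observed, min_selected = 50) {
  idx <- if (is.list(selected)) selected$index else selected
  dist <- if (is.list(selected)) selected$distance else
    rep(1, length(idx))
  keep <- table$scenario[idx] == scenario_name
  idx <- idx[keep]; dist <- dist[keep]
  if (length(idx) < min_selected)
    stop("only ", length(idx), " accepted draws for ", scenario_name,
         "; widen the tolerance or enlarge the reference table")
  P <- do.call(rbind, table$params[idx])
  bounds <- .param_bounds(set, scenario_name)
  bounds <- bounds[colnames(P)]
  dmax <- max(dist)
  w <- if (dmax > 0) 1 - (dist / dmax)^2 else rep(1, length(dist))
  w[w <= 0] <- min(w[w > 0], 1e-6)
  X <- .drop_constant(table$stats[idx, , drop = FALSE])
  X <- sweep(X, 2, observed[colnames(X)], "-")
  sdx <- apply(X, 2, sd)
  X <- sweep(X, 2, ifelse(sdx > 0, sdx, 1), "/")
  # regress on the leading principal components of the local cloud (the
  # observed point maps to the origin); capping the dimension relative to
  # the number of accepted draws keeps the adjustment from overfitting
  n_comp <- max(1, min(10, floor(length(idx) / 10), ncol(X)))
  rot <- svd(X, nu = 0, nv = n_comp)$v
  Xr <- X %*% rot
  adj <- P
  for (j in seq_len(ncol(P))) {
    b <- bounds[[j]]
    if (b["max"] - b["min"] <= 0 || var(P[, j]) == 0) {
      adj[, j] <- P[, j]
      next
    }
    u <- .to_unit(P[, j], b)
    yl <- log(u / (1 - u))
    fit <- lm(yl ~ Xr, weights = w)
    bet <- coef(fit)[-1]
    bet[is.na(bet)] <- 0  # collinear axes drop out of the adjustment
    # rescale residuals for the degrees of freedom the regression absorbs,
    # so the adjusted spread is not biased narrow
    mu_hat <- coef(fit)[1]
    infl <- sqrt(length(yl) / max(1, length(yl) - n_comp - 1))
    resid_adj <- mu_hat + infl * (yl - Xr %*% bet - mu_hat)
    adj[, j] <- .from_unit(1 / (1 + exp(-resid_adj)), b)
  }
  summ <- do.call(rbind, lapply(seq_len(ncol(adj)), function(j) {
    v <- adj[, j]
    qs <- .weighted_quantile(v, w, c(0.025, 0.05, 0.5, 0.95, 0.975))
    mode <- if (var(v) > 0) {
      dn <- suppressWarnings(density(v, weights = w / sum(w)))
      dn$x[which.max(dn$y)]
    } else v[1]
    data.frame(parameter = colnames(adj)[j],
               mean = weighted.mean(v, w), median = qs[3], mode = mode,
               q2.5 = qs[1], q5 = qs[2], q95 = qs[4], q97.5 = qs[5],
               stringsAsFactors = FALSE)
  }))
  structure(list(adjusted = adj, raw = P, weights = w, summary = summ,
                 scenario = scenario_name), class = "posterior_sample")
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

#' Posterior predictive goodness-of-fit check
#'
#' Simulates datasets with parameters drawn from the posterior sample
#' (respecting the scenario's conditions by resampling) and locates each
#' observed statistic in its simulated distribution; a statistic is
#' flagged when its two-tailed tail probability falls below `alpha`.
#'
#' @param set A [scenario_set()].
#' @param posterior A `posterior_sample` from [estimate_parameters()].
#' @param observed Observed summary-statistic vector.
#' @param n_sims Number of posterior predictive simulations.
#' @param seed Optional integer seed.
#' @param alpha Flagging threshold (default 0.05).
#' @return Data frame per statistic: `observed`, `p_value`, `flagged`.
#' @export
posterior_predictive_check <- function(set, posterior, observed,
                                       n_sims = 100, seed = NULL,
                                       alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  sc <- set$scenarios[[posterior$scenario]]
  design <- set$design
  n_acc <- nrow(posterior$adjusted)
  pr <- posterior$weights / sum(posterior$weights)
  sims <- matrix(NA_real_, n_sims, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (s in seq_len(n_sims)) {
    for (try in seq_len(1000)) {
      par <- posterior$adjusted[sample.int(n_acc, 1, prob = pr), ]
      env <- list2env(as.list(par))
      ok <- all(vapply(sc$conditions, function(cn)
        isTRUE(eval(parse(text = cn), envir = env)), logical(1)))
      if (ok) break
      if (try == 1000)
        stop("posterior draws violate the scenario conditions")
    }
    dem <- realize_scenario(sc, par, set$gen_time)
    model <- mutation_model(mu_mic = par[["mu_mic"]],
                            p_gsm = par[["p_gsm"]],
                            range = design$allele_range,
                            mu_mt = par[["mu_mt"]],
                            kappa = par[["kappa"]])
    raw <- .sim_raw(dem, model, design)
    sims[s, ] <- .ss_from_raw(raw, design)
  }
  p <- vapply(seq_along(observed), function(j) {
    v <- sims[, j]
    r <- (sum(v < observed[j]) + 0.5 * sum(v == observed[j])) / n_sims
    min(1, 2 * min(r, 1 - r))
  }, numeric(1))
  data.frame(statistic = names(observed), observed = unname(observed),
             p_value = p, flagged = p < alpha, stringsAsFactors = FALSE)
}
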