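#' Define a parameter-estimation problem
#'
#' Couples one or more experiments (reaction network + observed TGN
#' profile) to a shared kinetic parameter vector.  Free parameters are,
#' for every rule active in at least one experiment, the turnover `Kf`
#' and acceptor constant `Km`; per enzyme the donor constant `Kmd`; and
#' per enzyme and localized compartment the enzyme concentration `E`.
#' All parameters share one box bound (default \eqn{[10^{-6}, 10^5]}).
#' In experiments that do not use an enzyme its concentration is forced
#' to zero regardless of the candidate value.
#'
#' Each experiment is weighted by \eqn{1/\sigma^2}, where \eqn{\sigma}
#' is the standard deviation of its observed profile values (the
#' standard-deviation weighting of common parameter-estimation tools).
#'
#' @param experiments List of experiments; each a list with `name`,
#'   `network` (a `"glyconet"`) and `observed` (named numeric, canonical
#'   structure string -> relative abundance in percent).
#' @param layout A `"golgi_layout"` shared by all experiments.
#' @param ruleset The rule set the networks were built from.
#' @param lower,upper Box bounds for every free parameter.
#' @return Object of class `"fit_problem"`.
#' @export
fit_problem <- function(experiments, layout = golgi_layout(),
                        ruleset = default_ruleset(),
                        lower = 1e-6, upper = 1e5) {
  stopifnot(length(experiments) >= 1L, lower > 0, upper > lower)
  for (ex in experiments) {
    stopifnot(!is.null(ex$name), inherits(ex$network, "glyconet"),
              is.numeric(ex$observed), length(ex$observed) >= 1L)
    miss <- setdiff(names(ex$observed), ex$network$species)
    if (length(miss))
      stop("experiment '", ex$name, "': observed structures not in network: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  rules <- unique(unlist(lapply(experiments, function(ex)
    ex$network$active_rule_ids)))
  enz_of <- vapply(ruleset$rules[rules], function(r) r$enzyme, character(1))
  enzymes <- unique(enz_of)
  exp_enzymes <- lapply(experiments, function(ex)
    unique(vapply(ruleset$rules[ex$network$active_rule_ids],
                  function(r) r$enzyme, character(1))))
  e_names <- character(0)
  for (e in enzymes)
    for (cc in layout$compartments)
      if (layout$localization[e, cc] == 1L)
        e_names <- c(e_names, paste0("E.", e, ".", cc))
  par_names <- c(paste0("Kf.", rules), paste0("Km.", rules),
                 paste0("Kmd.", enzymes), e_names)
  weights <- vapply(experiments, function(ex) {
    s <- stats::sd(ex$observed)
    if (is.na(s) || s == 0) 1 else 1 / s^2
  }, numeric(1))
  structure(list(experiments = experiments, layout = layout,
                 ruleset = ruleset, rules = rules, enzymes = enzymes,
                 rule_enzyme = enz_of, exp_enzymes = exp_enzymes,
                 par_names = par_names, lower = lower, upper = upper,
                 weights = weights),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat("<fit_problem> ", length(x$experiments), " experiment(s), ",
      length(x$par_names), " free parameters in [", x$lower, ", ",
      x$upper, "]\n", sep = "")
  invisible(x)
}

# expand a named parameter vector into a kinetic_params for one experiment
# (enzymes absent from the experiment are masked to zero concentration)
.params_for_experiment <- function(problem, par, i) {
  rules <- problem$rules
  enzymes <- problem$enzymes
  Kf <- stats::setNames(par[paste0("Kf.", rules)], rules)
  Km <- stats::setNames(par[paste0("Km.", rules)], rules)
  Kmd <- stats::setNames(par[paste0("Kmd.", enzymes)], enzymes)
  E <- matrix(0, length(enzymes), 4L,
              dimnames = list(enzymes, problem$layout$compartments))
  for (nm in grep("^E\\.", problem$par_names, value = TRUE)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    E[parts[2L], parts[3L]] <- par[[nm]]
  }
  absent <- setdiff(enzymes, problem$exp_enzymes[[i]])
  E[absent, ] <- 0
  kinetic_params(Kf, Km, Kmd, E, problem$layout)
}

#' Flatten a kinetic parameter set into a problem's parameter vector
#'
#' Inverse of the expansion used internally by [objective()]: extracts
#' the problem's free parameters from a `"kinetic_params"` (e.g. the
#' ground truth of a synthetic scenario).
#'
#' @param problem A `"fit_problem"`.
#' @param params A `"kinetic_params"` covering the problem's rules.
#' @return Named numeric vector ordered as `problem$par_names`.
#' @export
params_to_vector <- function(problem, params) {
  v <- stats::setNames(numeric(length(problem$par_names)), problem$par_names)
  for (r in problem$rules) {
    v[paste0("Kf.", r)] <- params$Kf[[r]]
    v[paste0("Km.", r)] <- params$Km[[r]]
  }
  for (e in problem$enzymes) v[paste0("Kmd.", e)] <- params$Kmd[[e]]
  for (nm in grep("^E\\.", problem$par_names, value = TRUE)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    v[nm] <- params$E[parts[2L], parts[3L]]
  }
  v
}

#' Simulate all experiments of a problem at a candidate parameter vector
#' @param problem A `"fit_problem"`.
#' @param par Named parameter vector (linear scale).
#' @param ... Passed to [simulate_golgi()].
#' @return Named list of TGN profiles (one per experiment).
#' @export
simulate_problem <- function(problem, par, ...) {
  out <- vector("list", length(problem$experiments))
  names(out) <- vapply(problem$experiments, `[[`, "", "name")
  for (i in seq_along(problem$experiments)) {
    p <- .params_for_experiment(problem, par, i)
    sim <- simulate_golgi(problem$experiments[[i]]$network, p,
                          problem$layout, ruleset = problem$ruleset, ...)
    out[[i]] <- sim$tgn_profile
  }
  out
}

#' Weighted least-squares objective
#'
#' Sum over experiments and observed structures of
#' \eqn{w_i \, (\mathrm{sim}\% - \mathrm{obs}\%)^2}, with the simulated
#' TGN profile normalized to 100 over all network species.  A failed
#' simulation yields `Inf` (the candidate is rejected).
#'
#' @inheritParams simulate_problem
#' @return Non-negative scalar (or `Inf`).
#' @export
objective <- function(problem, par) {
  tot <- 0
  for (i in seq_along(problem$experiments)) {
    ex <- problem$experiments[[i]]
    prof <- tryCatch({
      p <- .params_for_experiment(problem, par, i)
      simulate_golgi(ex$network, p, problem$layout,
                     nt = 2L, ruleset = problem$ruleset)$tgn_profile
    }, error = function(e) NULL)
    if (is.null(prof)) return(Inf)
    r <- prof[names(ex$observed)] - ex$observed
    tot <- tot + problem$weights[i] * sum(r^2)
  }
  tot
}

#' Fit a kinetic model by a stochastic-ranking evolution strategy
#'
#' A \eqn{(\mu, \lambda)} evolution strategy with self-adaptive
#' per-parameter step sizes, searched on the \eqn{\log_{10}} scale
#' (kinetic constants are scale parameters spanning eleven decades), with
#' log-uniform initialization inside the bounds and bound repair by
#' reflection.  With only box constraints the stochastic ranking reduces
#' to objective-sorted truncation selection.  Deterministic given `seed`;
#' the best-ever candidate is returned.
#'
#' @param problem A `"fit_problem"`.
#' @param population Offspring per generation (lambda, >= 10).
#' @param generations Maximum generations (>= 1).
#' @param seed Integer seed controlling all randomness of the fit.
#' @param mu Parents kept per generation (default `population/4`).
#' @param stall_tol,stall_generations Early stopping: stop when the best
#'   objective improves by less than `stall_tol` over
#'   `stall_generations` consecutive generations.
#' @return Object of class `"oglycofit"`; see [summary.oglycofit()].
#' @seealso [fit_oglycan_model()] for the high-level interface.
#' @export
sres_fit <- function(problem, population = 20L, generations = 500L,
                     seed = 1L, mu = NULL,
                     stall_tol = 1e-10, stall_generations = 50L) {
  stopifnot(inherits(problem, "fit_problem"),
            population >= 10L, generations >= 1L)
  n <- length(problem$par_names)
  mu <- if (is.null(mu)) max(2L, population %/% 4L) else as.integer(mu)
  lb <- log10(problem$lower)
  ub <- log10(problem$upper)
  tau_g <- 1 / sqrt(2 * n)
  tau_l <- 1 / sqrt(2 * sqrt(n))
  sigma0 <- (ub - lb) / sqrt(n)

  set.seed(as.integer(seed))
  eval_z <- function(z) objective(problem,
                                  stats::setNames(10^z, problem$par_names))
  reflect <- function(z) {
    for (k in 1:10) {
      over <- z > ub; z[over] <- 2 * ub - z[over]
      under <- z < lb; z[under] <- 2 * lb - z[under]
      if (!any(z > ub | z < lb)) break
    }
    pmin(pmax(z, lb), ub)
  }

  Z <- matrix(stats::runif(population * n, lb, ub), nrow = population)
  S <- matrix(sigma0, population, n)
  f <- apply(Z, 1L, eval_z)
  ord <- order(f)
  best_z <- Z[ord[1L], ]
  best_f <- f[ord[1L]]
  history <- numeric(0)
  stall <- 0L
  last_best <- best_f

  for (g in seq_len(generations)) {
    parents_Z <- Z[ord[seq_len(mu)], , drop = FALSE]
    parents_S <- S[ord[seq_len(mu)], , drop = FALSE]
    Z <- matrix(0, population, n)
    S <- matrix(0, population, n)
    for (j in seq_len(population)) {
      a <- sample.int(mu, 1L)
      b <- sample.int(mu, 1L)
      sig <- 0.5 * (parents_S[a, ] + parents_S[b, ])  # intermediate recombination
      sig <- sig * exp(tau_g * stats::rnorm(1L) + tau_l * stats::rnorm(n))
      sig <- pmin(sig, ub - lb)
      z <- reflect(parents_Z[a, ] + sig * stats::rnorm(n))
      Z[j, ] <- z
      S[j, ] <- sig
    }
    f <- apply(Z, 1L, eval_z)
    ord <- order(f)
    if (f[ord[1L]] < best_f) {
      best_f <- f[ord[1L]]
      best_z <- Z[ord[1L], ]
    }
    history <- c(history, best_f)
    if (last_best - best_f < stall_tol) stall <- stall + 1L else stall <- 0L
    last_best <- best_f
    if (stall >= stall_generations) break
  }

  par <- stats::setNames(10^best_z, problem$par_names)
  profiles <- simulate_problem(problem, par)
  resid <- lapply(seq_along(problem$experiments), function(i) {
    ex <- problem$experiments[[i]]
    sim <- profiles[[i]][names(ex$observed)]
    data.frame(experiment = ex$name, structure = names(ex$observed),
               observed = unname(ex$observed), simulated = unname(sim),
               residual = unname(sim - ex$observed),
               stringsAsFactors = FALSE)
  })
  structure(list(par = par, objective = best_f, history = history,
                 seed = as.integer(seed), problem = problem,
                 profiles = profiles,
                 residual_table = do.call(rbind, resid),
                 population = population, mu = mu,
                 generations_run = length(history),
                 weighting = "1/sd(observed)^2"),
            class = "oglycofit")
}

#' Jointly fit several experiments with shared parameters
#'
#' Convenience wrapper: builds one [fit_problem()] over all experiments
#' (one shared parameter vector, per-experiment enzyme masking) and runs
#' [sres_fit()].
#'
#' @inheritParams fit_problem
#' @inheritParams sres_fit
#' @param ... Passed to [sres_fit()].
#' @return An `"oglycofit"`.
#' @export
joint_fit <- function(experiments, layout = golgi_layout(),
                      ruleset = default_ruleset(), ...) {
  sres_fit(fit_problem(experiments, layout, ruleset), ...)
}

#' Fit the O-glycosylation kinetic model to observed glycan profiles
#'
#' High-level fitting interface.  For each named experiment the reaction
#' network is generated from the bundled configuration (transfected plus
#' required enzymes), the observed profile is attached, and all kinetic
#' constants are estimated jointly by [sres_fit()].
#'
#' @param observed Named list: experiment name -> named numeric vector of
#'   observed relative abundances (percent) keyed by structure string.
#'   Structure spellings are canonicalized.
#' @param experiments Experiment configurations from
#'   [load_experiments()]; defaults to the bundled 25.
#' @param layout,ruleset Model configuration.
#' @param max_residues Network expansion cutoff.
#' @param ... Passed to [sres_fit()] (population, generations, seed, ...).
#' @return An `"oglycofit"` with print/summary/coef/fitted/residuals/
#'   predict/plot methods.
#' @examples
#' \donttest{
#' sc <- generate_scenario("CHO-WT", seed = 7)
#' fit <- fit_oglycan_model(list("CHO-WT" = sc$profile),
#'                          generations = 100, seed = 1)
#' summary(fit)
#' }
#' @export
fit_oglycan_model <- function(observed, experiments = load_experiments(),
                              layout = golgi_layout(),
                              ruleset = default_ruleset(),
                              max_residues = 10L, ...) {
  stopifnot(is.list(observed), !is.null(names(observed)))
  exps <- lapply(names(observed), function(nm) {
    cfg <- experiment_config(nm, experiments)
    net <- build_network(ruleset, cfg$active_rule_ids, max_residues)
    obs <- observed[[nm]]
    names(obs) <- vapply(names(obs), function(s) format(parse_glycan(s)), "")
    list(name = nm, network = net, observed = obs)
  })
  sres_fit(fit_problem(exps, layout, ruleset), ...)
}
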