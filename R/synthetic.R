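# draw a parameter set for an explicit rule list (shared across networks)
.random_params_for_rules <- function(rule_ids, layout, ruleset,
                                     lower = 1e-6, upper = 1e5) {
  enz <- unique(vapply(ruleset$rules[rule_ids], function(r) r$enzyme,
                       character(1)))
  draw <- function(n) 10^stats::runif(n, log10(lower), log10(upper))
  kinetic_params(
    Kf = stats::setNames(draw(length(rule_ids)), rule_ids),
    Km = stats::setNames(draw(length(rule_ids)), rule_ids),
    Kmd = stats::setNames(draw(length(enz)), enz),
    E = matrix(draw(length(enz) * 4L), nrow = length(enz),
               dimnames = list(enz, layout$compartments)),
    layout = layout)
}

.mask_params <- function(params, enzymes_present) {
  absent <- setdiff(rownames(params$E), enzymes_present)
  params$E[absent, ] <- 0
  params
}

.noisy_profile <- function(profile, sigma_noise) {
  if (sigma_noise > 0) {
    profile <- pmax(profile + stats::rnorm(length(profile), 0, sigma_noise), 0)
    if (sum(profile) <= 0) return(NULL)
    profile <- 100 * profile / sum(profile)
  }
  profile[profile > 0]
}

#' Generate a synthetic observed profile for an experiment
#'
#' Draws a ground-truth kinetic parameter set (log-uniform within the
#' estimation bounds), simulates the experiment's network through the
#' Golgi model, takes the TGN profile, optionally adds truncated-Gaussian
#' noise on the percentage scale (renormalized to 100), and packages the
#' result as an observed-profile stand-in.  Draws for which the root
#' retains more than 99 percent (an uninformative pathway) are rejected
#' and redrawn, up to 100 times.
#'
#' Generation is a pure function of `(experiment, seed, sigma_noise)`.
#'
#' @param experiment Experiment name or alias (see [load_experiments()]).
#' @param seed Integer seed.
#' @param sigma_noise Noise standard deviation in percentage points
#'   (default 0: the profile is exactly simulable).
#' @param ruleset,layout,experiments Model configuration.
#' @param max_residues Network expansion cutoff.
#' @return Object of class `"glyco_scenario"`: list with `experiment`,
#'   `seed`, `sigma_noise`, `network`, `true_params`, and `profile`
#'   (named percentages over structures with nonzero abundance).
#' @export
generate_scenario <- function(experiment, seed, sigma_noise = 0,
                              ruleset = default_ruleset(),
                              layout = golgi_layout(),
                              experiments = load_experiments(),
                              max_residues = 10L) {
  cfg <- experiment_config(experiment, experiments)
  net <- build_network(ruleset, cfg$active_rule_ids, max_residues)
  set.seed(as.integer(seed))
  for (try in seq_len(100L)) {
    params <- random_params(net, layout, ruleset)
    prof <- tryCatch(
      simulate_golgi(net, params, layout, ruleset = ruleset)$tgn_profile,
      error = function(e) NULL)
    if (is.null(prof) || prof[[net$root]] > 99) next
    prof <- .noisy_profile(prof, sigma_noise)
    if (is.null(prof)) next
    return(structure(list(experiment = cfg$name, seed = as.integer(seed),
                          sigma_noise = sigma_noise, network = net,
                          true_params = params, profile = prof),
                     class = "glyco_scenario"))
  }
  stop("no informative scenario for '", cfg$name, "' within 100 draws ",
       "(root retained > 99% in every draw)", call. = FALSE)
}

#' @export
print.glyco_scenario <- function(x, ...) {
  cat("<glyco_scenario> ", x$experiment, " (seed ", x$seed,
      ", sigma ", x$sigma_noise, ")\n", sep = "")
  for (i in order(-x$profile))
    cat(sprintf("  %6.2f%%  %s\n", x$profile[i], names(x$profile)[i]))
  invisible(x)
}

#' Synthetic four-experiment suite with one shared truth
#'
#' Generates scenarios for the four jointly modeled cell lines (CHO-WT,
#' Slex on C3, Slex on exC1, A4GlcNAc on C1) from a single shared
#' ground-truth parameter vector over the union of their rule sets; in
#' each experiment the concentrations of enzymes it does not use are
#' masked to zero.  Draws are rejected until every experiment is
#' informative (root below 99 percent everywhere), up to 100 times.
#'
#' @inheritParams generate_scenario
#' @return List of four `"glyco_scenario"` objects sharing
#'   `true_params`.
#' @export
four_experiment_suite <- function(seed, sigma_noise = 0,
                                  ruleset = default_ruleset(),
                                  layout = golgi_layout(),
                                  experiments = load_experiments(),
                                  max_residues = 10L) {
  nms <- c("CHO-WT", "Slex on C3", "Slex on exC1", "A4GlcNAc on C1")
  cfgs <- lapply(nms, experiment_config, experiments = experiments)
  nets <- lapply(cfgs, function(cfg)
    build_network(ruleset, cfg$active_rule_ids, max_residues))
  all_rules <- unique(unlist(lapply(nets, `[[`, "active_rule_ids")))
  enz_by_exp <- lapply(nets, function(n)
    unique(vapply(ruleset$rules[n$active_rule_ids], function(r) r$enzyme, "")))
  set.seed(as.integer(seed))
  for (try in seq_len(100L)) {
    shared <- .random_params_for_rules(all_rules, layout, ruleset)
    profs <- vector("list", length(nms))
    ok <- TRUE
    for (i in seq_along(nms)) {
      p <- .mask_params(shared, enz_by_exp[[i]])
      prof <- tryCatch(
        simulate_golgi(nets[[i]], p, layout, ruleset = ruleset)$tgn_profile,
        error = function(e) NULL)
      if (is.null(prof) || prof[[nets[[i]]$root]] > 99) { ok <- FALSE; break }
      prof <- .noisy_profile(prof, sigma_noise)
      if (is.null(prof)) { ok <- FALSE; break }
      profs[[i]] <- prof
    }
    if (!ok) next
    return(lapply(seq_along(nms), function(i)
      structure(list(experiment = cfgs[[i]]$name, seed = as.integer(seed),
                     sigma_noise = sigma_noise, network = nets[[i]],
                     true_params = shared, profile = profs[[i]]),
                class = "glyco_scenario")))
  }
  stop("no informative four-experiment suite within 100 draws", call. = FALSE)
}

#' Build a fit problem from synthetic scenarios
#'
#' @param scenarios A `"glyco_scenario"` or list of them.
#' @param layout,ruleset Model configuration.
#' @return A `"fit_problem"` whose observations are the scenario
#'   profiles.
#' @export
scenario_problem <- function(scenarios, layout = golgi_layout(),
                             ruleset = default_ruleset()) {
  if (inherits(scenarios, "glyco_scenario")) scenarios <- list(scenarios)
  exps <- lapply(scenarios, function(sc)
    list(name = sc$experiment, network = sc$network, observed = sc$profile))
  fit_problem(exps, layout, ruleset)
}
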