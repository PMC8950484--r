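#' @export
print.oglycofit <- function(x, ...) {
  cat("O-glycosylation kinetic model fit (stochastic-ranking ES)\n")
  cat("  experiments: ",
      paste(vapply(x$problem$experiments, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  cat("  free parameters: ", length(x$par),
      "   weighted SSR: ", format(x$objective, digits = 6), "\n", sep = "")
  cat("  generations: ", x$generations_run, " (population ", x$population,
      ", mu ", x$mu, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Summarize a fitted O-glycosylation model
#'
#' @param object An `"oglycofit"`.
#' @param ... Unused.
#' @return The object, invisibly; prints the fit summary and the
#'   per-structure observed/simulated table.
#' @export
summary.oglycofit <- function(object, ...) {
  print(object)
  cat("\nPer-structure fit (percent of TGN profile):\n")
  tab <- object$residual_table
  tab$observed <- round(tab$observed, 2)
  tab$simulated <- round(tab$simulated, 2)
  tab$residual <- round(tab$residual, 2)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.oglycofit <- function(object, ...) object$par

#' @export
fitted.oglycofit <- function(object, ...) object$profiles

#' @export
residuals.oglycofit <- function(object, ...) {
  stats::setNames(object$residual_table$residual,
                  object$residual_table$structure)
}

#' Predict TGN glycan profiles from a fitted model
#'
#' Simulates the fitted model.  With `newdata = NULL` the fitted
#' experiments are re-simulated; otherwise `newdata` names bundled
#' experiment configurations (their networks are generated and simulated
#' under the fitted shared parameters, with enzyme concentrations of
#' enzymes the fit never saw set to zero).
#'
#' @param object An `"oglycofit"`.
#' @param newdata `NULL` or character vector of experiment names.
#' @param experiments Experiment bundle used to resolve `newdata`.
#' @param ... Passed to [simulate_golgi()].
#' @return Named list of TGN profiles (percent).
#' @export
predict.oglycofit <- function(object, newdata = NULL,
                              experiments = load_experiments(), ...) {
  if (is.null(newdata))
    return(simulate_problem(object$problem, object$par, ...))
  prob <- object$problem
  out <- list()
  for (nm in newdata) {
    cfg <- experiment_config(nm, experiments)
    net <- build_network(prob$ruleset, cfg$active_rule_ids)
    extra <- setdiff(net$active_rule_ids, prob$rules)
    if (length(extra))
      stop("experiment '", nm, "' uses rules outside the fitted set: ",
           paste(extra, collapse = ", "), call. = FALSE)
    p <- .params_for_experiment(prob, object$par, 1L)
    sim <- simulate_golgi(net, p, prob$layout, ruleset = prob$ruleset, ...)
    out[[nm]] <- sim$tgn_profile
  }
  out
}

#' Plot observed versus simulated TGN profiles
#'
#' One grouped bar panel per experiment: observed relative abundances
#' next to the fitted model's simulated abundances for every observed
#' structure.
#'
#' @param x An `"oglycofit"`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.oglycofit <- function(x, ...) {
  tab <- x$residual_table
  exps <- unique(tab$experiment)
  old <- graphics::par(mfrow = c(length(exps), 1L),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (e in exps) {
    sub <- tab[tab$experiment == e, ]
    m <- rbind(observed = sub$observed, simulated = sub$simulated)
    lab <- ifelse(nchar(sub$structure) > 28,
                  paste0(substr(sub$structure, 1, 25), "..."),
                  sub$structure)
    graphics::barplot(m, beside = TRUE, names.arg = lab, las = 2,
                      cex.names = 0.6, ylab = "% of TGN profile",
                      main = e, legend.text = rownames(m),
                      args.legend = list(x = "topright", bty = "n"), ...)
  }
  invisible(x)
}
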