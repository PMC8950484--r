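# Precompute, for one compartment, everything the rate law needs:
# the subset of network reactions whose enzyme is present and whose donor
# is nonzero there, with donor-saturation factors folded into an activity
# coefficient A = Kf * E * n_sites * (D/Kmd)/(1 + D/Kmd).  The remaining
# state dependence is S_sub/Km over 1 + sum_k S_k/Km_k (acceptor
# competition within each enzyme).
.compartment_tables <- function(network, params, layout, comp,
                                ruleset = default_ruleset()) {
  rx <- network$reactions
  if (nrow(rx) == 0L)
    return(list(n = 0L))
  rules <- ruleset$rules[rx$rule_id]
  donors <- vapply(rules, function(r) r$donor, character(1))
  D <- layout$donors[donors, comp]
  E <- params$E[rx$enzyme, comp]
  Kmd <- params$Kmd[rx$enzyme]
  Kf <- params$Kf[rx$rule_id]
  Km <- params$Km[rx$rule_id]
  # an instance competes for its enzyme whenever enzyme and donor are
  # present, even if its own turnover is zero
  keep <- unname(E > 0 & D > 0)
  if (!any(keep))
    return(list(n = 0L))
  dfac <- (D[keep] / Kmd[keep]) / (1 + D[keep] / Kmd[keep])
  B <- unname(Kf[keep] * E[keep] * dfac)
  sub <- match(rx$substrate, network$species)[keep]
  prod <- match(rx$product, network$species)[keep]
  enz <- as.integer(factor(rx$enzyme[keep]))
  nsites <- rx$n_sites[keep]
  ns <- length(network$species)
  nr <- sum(keep)
  M <- matrix(0, ns, nr)
  for (j in seq_len(nr)) {
    M[sub[j], j] <- M[sub[j], j] - 1
    M[prod[j], j] <- M[prod[j], j] + 1
  }
  list(n = nr, B = B, xcoef = nsites / unname(Km[keep]),
       sub = sub, prod = prod, enz = enz, M = M)
}

# smooth positive part: keeps the competition sum non-negative while
# staying C-infinity through S = 0, which the stiff corrector requires
.spos <- function(x) 0.5 * (x + sqrt(x * x + 1e-20))
.dspos <- function(x) 0.5 * (1 + x / sqrt(x * x + 1e-20))

.rates <- function(tab, y) {
  # numerator keeps raw S: a tiny negative excursion yields v < 0, which
  # refills the pool (self-correcting), so no hard clamp is needed
  x <- y[tab$sub] * tab$xcoef
  comp <- rowsum(.spos(x), tab$enz)[tab$enz, 1L]
  tab$B * x / (1 + comp)
}

.rhs_factory <- function(tab) {
  if (tab$n == 0L) return(function(t, y, p) list(rep(0, length(y))))
  function(t, y, p) list(drop(tab$M %*% .rates(tab, y)))
}

# analytic Jacobian of the compartment RHS; rate constants drawn over many
# decades make the system too stiff for a finite-difference Jacobian
.jac_factory <- function(tab, ns) {
  if (tab$n == 0L) return(function(t, y, p) matrix(0, ns, ns))
  function(t, y, p) {
    x <- y[tab$sub] * tab$xcoef
    comp <- rowsum(.spos(x), tab$enz)[tab$enz, 1L]
    denom <- 1 + comp
    dsp <- .dspos(x)
    nr <- tab$n
    dv <- matrix(0, nr, ns)
    for (j in seq_len(nr))
      dv[j, tab$sub[j]] <- dv[j, tab$sub[j]] + tab$B[j] * tab$xcoef[j] / denom[j]
    for (k in seq_len(nr)) {
      same <- which(tab$enz == tab$enz[k])
      for (j in same)
        dv[j, tab$sub[k]] <- dv[j, tab$sub[k]] -
          tab$B[j] * x[j] * dsp[k] * tab$xcoef[k] / denom[j]^2
    }
    tab$M %*% dv
  }
}

#' Reaction rate of one rule instance in one compartment
#'
#' Evaluates the competing-substrate Michaelis--Menten rate law for the
#' reaction `rule_id` acting on `substrate` in compartment `comp`:
#' \deqn{v = \frac{K_f E \, (D/K_{md}) \, (S_j/K_m)}
#'            {(1 + D/K_{md}) \, (1 + \sum_k S_k/K_{m,k})}}
#' where the competition sum runs over all species--rule pairs of the same
#' enzyme present in the compartment, \eqn{D} is the clamped donor
#' concentration, and \eqn{S_j} the substrate of this instance.  The rate
#' is zero when the enzyme is absent from the compartment or its donor
#' concentration there is zero.
#'
#' @param network A `"glyconet"`.
#' @param params A `"kinetic_params"`.
#' @param layout A `"golgi_layout"`.
#' @param rule_id Rule id of the reaction.
#' @param substrate Canonical substrate string.
#' @param comp Compartment name.
#' @param conc Named vector of species concentrations (uM); must cover
#'   all network species and be non-negative.
#' @param ruleset Rule set (for donor lookup).
#' @return Rate in uM/min.
#' @export
reaction_rate <- function(network, params, layout, rule_id, substrate, comp,
                          conc, ruleset = default_ruleset()) {
  y <- conc[network$species]
  if (anyNA(y)) stop("'conc' must name every network species", call. = FALSE)
  if (any(y < 0)) stop("negative concentration", call. = FALSE)
  rx <- network$reactions
  i <- which(rx$rule_id == rule_id & rx$substrate == substrate)
  if (length(i) != 1L)
    stop("no reaction '", rule_id, "' on '", substrate, "' in network",
         call. = FALSE)
  rule <- ruleset$rules[[rule_id]]
  D <- layout$donors[rule$donor, comp]
  E <- params$E[rx$enzyme[i], comp]
  if (D <= 0 || E <= 0) return(0)
  Kmd <- params$Kmd[rx$enzyme[i]]
  same <- which(rx$enzyme == rx$enzyme[i])
  # competition: every instance of this enzyme with nonzero donor here
  active <- vapply(same, function(j) {
    layout$donors[ruleset$rules[[rx$rule_id[j]]]$donor, comp] > 0
  }, logical(1))
  same <- same[active]
  compsum <- sum(y[rx$substrate[same]] / params$Km[rx$rule_id[same]] *
                   rx$n_sites[same])
  S <- y[[substrate]]
  unname(params$Kf[rule_id] * E * rx$n_sites[i] *
           (D / Kmd) / (1 + D / Kmd) * (S / params$Km[rule_id]) / (1 + compsum))
}

#' Assemble the ODE right-hand side for one compartment
#'
#' Maps the reaction network and rate law onto state equations
#' \eqn{dS_i/dt = \sum \text{producing} - \sum \text{consuming}} for the
#' given compartment, with donors clamped at their layout values.  The
#' returned function has the `deSolve` signature `function(t, y, parms)`.
#'
#' @inheritParams reaction_rate
#' @return A function suitable for [deSolve::lsoda()]; state order is
#'   `network$species`.
#' @export
assemble_system <- function(network, params, layout, comp,
                            ruleset = default_ruleset()) {
  .rhs_factory(.compartment_tables(network, params, layout, comp, ruleset))
}

#' Simulate glycan processing through the Golgi
#'
#' Integrates the kinetic model over the four compartments.  In the
#' default sequential-batch (plug-flow) mode the entire glycan content
#' starts in cis, reacts there for one residence time `tau`, is then
#' transferred wholesale to medial, and so on; the simulation stops at
#' `4 * tau` (22.24 min by default) and the relative abundances in the
#' TGN are reported.  In `"cstr"` mode the four compartments form a
#' continuous stirred-tank chain with inter-compartment flux
#' `(S[c-1] - S[c]) / tau` and no efflux from the TGN.
#'
#' @param network A `"glyconet"`.
#' @param params A `"kinetic_params"` covering the network's rules.
#' @param layout A `"golgi_layout"`.
#' @param mode `"batch"` (default) or `"cstr"`.
#' @param nt Stored time points per compartment (batch) or in total
#'   (cstr).
#' @param rtol,atol Integrator tolerances.
#' @param ruleset Rule set used to build the network.
#' @return Object of class `"golgi_sim"`: `trajectories` (data.frame:
#'   time, compartment, species, conc), `tgn_profile` (named percentages
#'   over species, summing to 100), `horizon`, `mode`.
#' @examples
#' \donttest{
#' net <- build_network(active_rule_ids = "C1GALT1")
#' p <- random_params(net)
#' sim <- simulate_golgi(net, p)
#' sim$tgn_profile
#' }
#' @export
simulate_golgi <- function(network, params, layout = golgi_layout(),
                           mode = c("batch", "cstr"), nt = 12L,
                           rtol = 1e-8, atol = 1e-10,
                           ruleset = default_ruleset()) {
  mode <- match.arg(mode)
  sp <- network$species
  ns <- length(sp)
  comps <- layout$compartments
  tau <- layout$tau
  horizon <- tau * length(comps)
  y0 <- stats::setNames(rep(0, ns), sp)
  y0[network$root] <- layout$initial_conc
  atol_abs <- atol * layout$initial_conc

  if (mode == "batch") {
    traj <- vector("list", length(comps))
    y <- y0
    for (ci in seq_along(comps)) {
      t0 <- (ci - 1L) * tau
      times <- seq(t0, t0 + tau, length.out = nt)
      tab <- .compartment_tables(network, params, layout, comps[ci], ruleset)
      rhs <- .rhs_factory(tab)
      jac <- .jac_factory(tab, ns)
      # BDF with the analytic Jacobian throughout: rate constants spanning
      # eleven decades defeat method-switching heuristics
      out <- deSolve::lsode(y, times, rhs, parms = NULL,
                            jacfunc = jac, jactype = "fullusr", mf = 21L,
                            rtol = rtol, atol = atol_abs, maxsteps = 50000L)
      if (attr(out, "istate")[1L] < 0)
        stop("integration failed in compartment '", comps[ci],
             "' near t = ", utils::tail(out[, 1L], 1L), " min", call. = FALSE)
      m <- out[, -1L, drop = FALSE]
      keep <- if (ci < length(comps)) seq_len(nrow(m) - 1L) else seq_len(nrow(m))
      traj[[ci]] <- data.frame(
        time = rep(out[keep, 1L], times = ns),
        compartment = comps[ci],
        species = rep(sp, each = length(keep)),
        conc = as.vector(m[keep, , drop = FALSE]),
        stringsAsFactors = FALSE)
      y <- stats::setNames(m[nrow(m), ], sp)
    }
    trajectories <- do.call(rbind, traj)
    final <- y
  } else {
    tabs <- lapply(comps, function(cc)
      .compartment_tables(network, params, layout, cc, ruleset))
    rhs <- function(t, y, p) {
      Y <- matrix(y, nrow = ns)
      dY <- matrix(0, ns, length(comps))
      for (ci in seq_along(comps)) {
        tab <- tabs[[ci]]
        if (tab$n > 0L) dY[, ci] <- drop(tab$M %*% .rates(tab, Y[, ci]))
        inflow <- if (ci == 1L) 0 else Y[, ci - 1L] / tau
        outflow <- if (ci == length(comps)) 0 else Y[, ci] / tau
        dY[, ci] <- dY[, ci] + inflow - outflow
      }
      list(as.vector(dY))
    }
    jacs <- lapply(tabs, .jac_factory, ns = ns)
    nc <- length(comps)
    jac <- function(t, y, p) {
      Y <- matrix(y, nrow = ns)
      J <- matrix(0, ns * nc, ns * nc)
      for (ci in seq_len(nc)) {
        ix <- (ci - 1L) * ns + seq_len(ns)
        J[ix, ix] <- jacs[[ci]](t, Y[, ci], p)
        if (ci < nc) {
          J[ix, ix] <- J[ix, ix] - diag(1 / tau, ns)
          J[ix + ns, ix] <- J[ix + ns, ix] + diag(1 / tau, ns)
        }
      }
      J
    }
    Y0 <- c(y0, rep(0, ns * (length(comps) - 1L)))
    times <- seq(0, horizon, length.out = max(nt * 4L, 8L))
    out <- deSolve::lsode(Y0, times, rhs, parms = NULL,
                          jacfunc = jac, jactype = "fullusr", mf = 21L,
                          rtol = rtol, atol = atol_abs, maxsteps = 50000L)
    if (attr(out, "istate")[1L] < 0)
      stop("integration failed (cstr mode)", call. = FALSE)
    m <- out[, -1L, drop = FALSE]
    trajectories <- do.call(rbind, lapply(seq_along(comps), function(ci) {
      cols <- (ci - 1L) * ns + seq_len(ns)
      data.frame(time = rep(out[, 1L], times = ns),
                 compartment = comps[ci],
                 species = rep(sp, each = nrow(m)),
                 conc = as.vector(m[, cols, drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
    final <- stats::setNames(m[nrow(m), (length(comps) - 1L) * ns + seq_len(ns)], sp)
  }

  prof <- pmax(final, 0)
  prof[prof < 1e-12] <- 0
  tgn_profile <- if (sum(prof) > 0) 100 * prof / sum(prof) else prof
  structure(list(trajectories = trajectories, tgn_profile = tgn_profile,
                 horizon = horizon, mode = mode, species = sp,
                 volume = layout$volume),
            class = "golgi_sim")
}

#' @export
print.golgi_sim <- function(x, ...) {
  cat("<golgi_sim> ", x$mode, " mode, horizon ", x$horizon, " min, ",
      length(x$species), " species\n", sep = "")
  top <- sort(x$tgn_profile[x$tgn_profile > 0], decreasing = TRUE)
  for (i in seq_len(min(6L, length(top))))
    cat(sprintf("  %6.2f%%  %s\n", top[i], names(top)[i]))
  invisible(x)
}

#' Total glycan amount at a time point
#'
#' Conservation diagnostic: the model's reactions are all 1:1 (one
#' acceptor in, one product out) and transport is lossless, so the total
#' glycan amount (concentration x compartment volume, summed over species
#' and compartments) is constant over the simulation.
#'
#' @param result A `"golgi_sim"`.
#' @param time Time in minutes (snapped to the nearest stored point).
#' @return Total amount in umol.
#' @export
total_glycan <- function(result, time) {
  tr <- result$trajectories
  stopifnot(time >= 0, time <= result$horizon)
  tt <- unique(tr$time)
  t0 <- tt[which.min(abs(tt - time))]
  sum(tr$conc[tr$time == t0]) * result$volume
}
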