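make_params <- function(net, Kf, Km, Kmd, E_by_enzyme, layout) {
  rs <- default_ruleset()
  ids <- net$active_rule_ids
  enz <- unique(vapply(rs$rules[ids], function(r) r$enzyme, ""))
  E <- matrix(0, length(enz), 4, dimnames = list(enz, layout$compartments))
  for (e in names(E_by_enzyme)) E[e, ] <- E_by_enzyme[[e]]
  kinetic_params(setNames(rep(Kf, length(ids)), ids),
                 setNames(rep(Km, length(ids)), ids),
                 setNames(rep(Kmd, length(enz)), enz),
                 E, layout)
}

test_that("reaction rates vanish without substrate, enzyme or donor", {
  lay <- golgi_layout()
  net <- chowt_network()
  set.seed(3)
  p <- random_params(net, lay)
  conc0 <- setNames(rep(0, length(net$species)), net$species)
  expect_identical(
    reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", conc0), 0)
  conc <- conc0; conc["GalNAcol"] <- 100
  # C1GALT1 is localized to cis only: zero enzyme in medial
  expect_identical(
    reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "medial", conc), 0)
  # ST3GAL sits in trans/TGN but CMP-NeuAc is absent from cis
  conc["Galβ1-3GalNAcol"] <- 10
  expect_identical(
    reaction_rate(net, p, lay, "ST3GAL_a", "Galβ1-3GalNAcol", "cis", conc), 0)
  expect_gt(
    reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", conc), 0)
  expect_error(
    reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", conc - 200),
    "negative")
})

test_that("the rate law reduces to classical Michaelis-Menten at saturating donor", {
  lay <- golgi_layout()
  net <- build_network(default_ruleset(), "C1GALT1")
  Kmd <- 100; Km <- 50; Kf <- 7; E <- 2
  lay$donors["UDP_Gal", "cis"] <- 1e3 * Kmd
  p <- make_params(net, Kf, Km, Kmd, list(C1GALT1 = c(1, 0, 0, 0) * E), lay)
  conc <- setNames(c(Km, 0), net$species)  # S = Km -> v ~ Kf E / 2
  v <- reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", conc)
  D <- 1e3 * Kmd
  expect_equal(v, Kf * E / 2 * D / (Kmd + D), tolerance = 1e-12)
  expect_equal(v, Kf * E / 2, tolerance = 0.01)
  # and against the explicit closed form over a sweep of substrate levels
  for (S in c(1, 20, 300)) {
    conc["GalNAcol"] <- S
    v <- reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", conc)
    expect_equal(v, (Kf * E * D / (Kmd + D)) * S / (Km + S), tolerance = 0.002)
  }
})

test_that("the assembled right-hand side matches hand-computed competing rates", {
  lay <- golgi_layout()
  rs <- default_ruleset()
  # C1GALT1 and B3GNT6 compete for the Tn root in cis, but are distinct
  # enzymes: each has its own competition denominator
  net <- build_network(rs, c("C1GALT1", "B3GNT6"))
  p <- make_params(net, 5, 40, 80,
                   list(C1GALT1 = c(2, 0, 0, 0), B3GNT6 = c(3, 0, 0, 0)), lay)
  rhs <- assemble_system(net, p, lay, "cis")
  y <- setNames(c(90, 4, 6), net$species)
  dy <- rhs(0, y, NULL)[[1]]
  vG <- reaction_rate(net, p, lay, "C1GALT1", "GalNAcol", "cis", y)
  vN <- reaction_rate(net, p, lay, "B3GNT6", "GalNAcol", "cis", y)
  dfac <- function(D, Kmd) (D / Kmd) / (1 + D / Kmd)
  expect_equal(vG, 5 * 2 * dfac(lay$donors["UDP_Gal", "cis"], 80) *
                 (90 / 40) / (1 + 90 / 40), tolerance = 1e-12)
  expect_equal(vN, 5 * 3 * dfac(lay$donors["UDP_GlcNAc", "cis"], 80) *
                 (90 / 40) / (1 + 90 / 40), tolerance = 1e-12)
  i <- match(net$species, net$species)
  expect_equal(dy[match("GalNAcol", net$species)], -(vG + vN), tolerance = 1e-12)
  expect_equal(sum(dy), 0, tolerance = 1e-12)

  # competition within one enzyme shares the denominator: ST6GALNAC in TGN
  net2 <- chowt_network()
  set.seed(8)
  p2 <- random_params(net2, lay)
  y2 <- setNames(c(10, 30, 5, 25, 20, 10), net2$species)
  va <- reaction_rate(net2, p2, lay, "ST6GALNAC_a", "GalNAcol", "TGN", y2)
  x <- function(rid, s) y2[[s]] / p2$Km[[rid]]
  compsum <- x("ST6GALNAC_a", "GalNAcol") +
    x("ST6GALNAC_b", "Galβ1-3GalNAcol") +
    x("ST6GALNAC_c", "NeuAcα2-3Galβ1-3GalNAcol")
  D <- lay$donors["CMP_NeuAc", "TGN"]
  expect_equal(va,
               p2$Kf[["ST6GALNAC_a"]] * p2$E["ST6GALNAC", "TGN"] *
                 (D / p2$Kmd[["ST6GALNAC"]]) / (1 + D / p2$Kmd[["ST6GALNAC"]]) *
                 x("ST6GALNAC_a", "GalNAcol") / (1 + compsum),
               tolerance = 1e-12)

  # empty network: identically zero right-hand side
  net0 <- build_network(rs, character())
  rhs0 <- assemble_system(net0, make_params(net0, 1, 1, 1, list(), lay),
                          lay, "cis")
  expect_identical(rhs0(0, c(GalNAcol = 50), NULL)[[1]], 0)
})

test_that("simulation horizon and trivial profile behave as configured", {
  lay <- golgi_layout()
  expect_equal(lay$tau, 5.56)
  expect_equal(lay$tau * length(lay$compartments), 22.24)
  net0 <- build_network(default_ruleset(), character())
  sim <- simulate_golgi(net0, make_params(net0, 1, 1, 1, list(), lay), lay)
  expect_equal(sim$horizon, 22.24)
  expect_equal(max(sim$trajectories$time), 22.24)
  expect_equal(unname(sim$tgn_profile["GalNAcol"]), 100)
  expect_equal(sum(sim$tgn_profile), 100)
})

test_that("glycan moles are conserved and concentrations stay non-negative", {
  lay <- golgi_layout()
  net <- chowt_network()
  set.seed(21)
  for (k in 1:5) {
    p <- random_params(net, lay)
    sim <- simulate_golgi(net, p, lay)
    expect_equal(total_glycan(sim, 0), 100 * 2.5, tolerance = 1e-9)
    for (t in c(5.56, 11.12, 22.24))
      expect_equal(total_glycan(sim, t), 250, tolerance = 1e-6)
    expect_gt(min(sim$trajectories$conc), -1e-9 * lay$initial_conc)
    # after the final transfer everything sits in the TGN
    last <- sim$trajectories[sim$trajectories$time == 22.24, ]
    expect_true(all(last$compartment == "TGN"))
    expect_equal(sum(last$conc) * lay$volume, 250, tolerance = 1e-6)
    expect_equal(sum(sim$tgn_profile), 100, tolerance = 1e-9)
  }
})

test_that("increasing a donor concentration never decreases its rule's rate", {
  lay <- golgi_layout()
  net <- chowt_network()
  set.seed(5)
  p <- random_params(net, lay)
  conc <- setNames(c(50, 30, 5, 10, 3, 2), net$species)
  prev <- -Inf
  for (D in c(100, 1000, 3000, 30000)) {
    lay$donors["CMP_NeuAc", "TGN"] <- D
    v <- reaction_rate(net, p, lay, "ST3GAL_a", "Galβ1-3GalNAcol", "TGN", conc)
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("one-rule batch kinetics match the closed-form MM solution", {
  lay <- golgi_layout()
  net <- build_network(default_ruleset(), "C1GALT1")
  Kf <- 10; E <- 1; Km <- 50; Kmd <- 100; D <- 1e5
  # enzyme and donor in every compartment: four sequential batches are one
  # continuous 22.24-min batch reactor
  lay$donors["UDP_Gal", ] <- D
  lay$localization["C1GALT1", ] <- 1L
  p <- make_params(net, Kf, Km, Kmd, list(C1GALT1 = rep(E, 4)), lay)
  sim <- simulate_golgi(net, p, lay)
  B <- Kf * E * D / (Kmd + D)
  S_end <- mm_batch_substrate(S0 = 100, Km = Km, B = B, t = 22.24)
  expect_equal(unname(sim$tgn_profile["GalNAcol"]), S_end,
               tolerance = 1e-3)
  expect_equal(unname(sim$tgn_profile["Galβ1-3GalNAcol"]), 100 - S_end,
               tolerance = 1e-3)
  # absolute percentage-point agreement better than 0.1
  expect_lt(abs(sim$tgn_profile[["GalNAcol"]] - S_end), 0.1)
})

test_that("the continuous (CSTR) transport mode conserves mass and lags the batch mode", {
  lay <- golgi_layout()
  net <- chowt_network()
  set.seed(2)
  p <- random_params(net, lay)
  sim <- simulate_golgi(net, p, lay, mode = "cstr")
  expect_equal(total_glycan(sim, 0), 250, tolerance = 1e-6)
  expect_equal(total_glycan(sim, 22.24), 250, tolerance = 1e-4)
  expect_identical(sim$mode, "cstr")
  expect_equal(sum(sim$tgn_profile), 100, tolerance = 1e-9)
  # material is still distributed over upstream compartments at the horizon
  tr <- sim$trajectories
  upstream <- tr[tr$time == max(tr$time) & tr$compartment != "TGN", ]
  expect_gt(sum(upstream$conc), 0)
})

test_that("SBML export is well-formed and covers species, donors and reactions", {
  skip_if_not_installed("xml2")
  lay <- golgi_layout()
  net <- chowt_network()
  set.seed(4)
  p <- random_params(net, lay)
  f <- tempfile(fileext = ".xml")
  export_sbml(net, p, lay, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  species <- xml2::xml_find_all(doc, ".//sbml:species", ns)
  expect_gte(length(species), length(net$species) * 4)
  bdry <- xml2::xml_attr(species, "boundaryCondition")
  expect_true(any(bdry == "true"))   # clamped donors
  rxn <- xml2::xml_find_all(doc, ".//sbml:reaction", ns)
  expect_gte(length(rxn), length(net$species) * 3)  # includes transport
  unlink(f)
})
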