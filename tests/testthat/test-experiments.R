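test_that("the experiment bundle holds 25 validated configurations", {
  exps <- load_experiments()
  expect_length(exps, 25L)
  expect_identical(anyDuplicated(vapply(exps, `[[`, "", "name")), 0L)

  cho <- experiment_config("CHO/CHO-WT")
  expect_length(cho$transfected, 0L)
  expect_identical(experiment_config("CHO-WT")$name, "CHO/CHO-WT")  # alias

  slex3 <- experiment_config("Slex on C3")
  expect_setequal(slex3$transfected, c("B3GNT6", "FUT7"))
  a4 <- experiment_config("A4GlcNAc on C1")
  expect_setequal(a4$transfected, "A4GNT")

  rs <- default_ruleset()
  flagged <- rs$enzymes$enzyme[rs$enzymes$transfected]
  for (e in exps) {
    expect_true(all(e$transfected %in% flagged))
    expect_true(all(e$active_rule_ids %in% names(rs$rules)))
    expect_gte(length(e$observed_structures), 1L)
  }
  expect_error(experiment_config("no such line"), "unknown experiment")
})

test_that("charge adjustment downweights sialylated species and renormalizes", {
  # the worked example: neutral 70 vs singly-charged 100 -> 70% / 30%
  p <- glycan_profile(c("Galb1-4GlcNAcb1-3GalNAcol", "NeuAca2-3Galb1-3GalNAcol"),
                      c(70, 100), kind = "raw_intensity")
  adj <- adjust_profile(p)
  expect_equal(attr(adj, "kind"), "adjusted")
  expect_equal(adj$value, c(70, 30), tolerance = 1e-12)

  # factors 1.0 / 0.3 / 0.4 by charge before renormalization
  p3 <- glycan_profile(
    c("Galb1-3GalNAcol",                       # charge 0
      "NeuAca2-3Galb1-3GalNAcol",              # charge 1
      "NeuAca2-3Galb1-3(NeuAca2-6)GalNAcol"),  # charge 2
    c(10, 10, 10), kind = "raw_intensity")
  adj3 <- adjust_profile(p3)
  expect_equal(adj3$value, 100 * c(10, 3, 4) / 17, tolerance = 1e-12)
  expect_equal(sum(adj3$value), 100, tolerance = 1e-6)

  # an all-neutral profile is only renormalized
  pn <- glycan_profile(c("Galb1-3GalNAcol", "GlcNAcb1-3GalNAcol"),
                       c(30, 10), kind = "raw_intensity")
  expect_equal(adjust_profile(pn)$value, c(75, 25))

  # double adjustment is impossible by contract
  expect_error(adjust_profile(adj), "already adjusted")
  # charge 3: no factor defined
  p4 <- glycan_profile("NeuAca2-36SGlcNAcb1-3(NeuAca2-6)GalNAcol", 10,
                       kind = "raw_intensity")
  expect_identical(p4$charge, 3L)
  expect_error(adjust_profile(p4), "charge > 2")
})

test_that("the bundled donor table carries the published concentrations", {
  lay <- golgi_layout()
  expect_identical(rownames(lay$donors),
                   c("CMP_NeuAc", "CMP_NeuGc", "GDP_Fuc", "UDP_GlcNAc",
                     "UDP_Gal", "UDP_GalNAc", "PAP_S"))
  expect_equal(unname(lay$donors["UDP_GlcNAc", ]), c(9143, 9143, 9143, 0))
  expect_equal(unname(lay$donors["PAP_S", ]), c(0, 920, 920, 920))
  expect_equal(unname(lay$donors["CMP_NeuAc", ]), c(0, 0, 3000, 3000))
  expect_equal(unname(lay$donors["CMP_NeuGc", ]), c(0, 0, 3000, 3000))
  expect_equal(unname(lay$donors["GDP_Fuc", ]), c(0, 5000, 5000, 0))
  expect_equal(unname(lay$donors["UDP_Gal", ]), c(3810, 0, 3810, 3810))
  expect_equal(unname(lay$donors["UDP_GalNAc", ]), c(0, 0, 3000, 0))
})

test_that("enzyme localization follows the compartmental division of labor", {
  lay <- golgi_layout()
  L <- lay$localization
  # core 1 / core 3 synthesis in cis
  expect_identical(unname(L["C1GALT1", "cis"]), 1L)
  expect_identical(unname(L["B3GNT6", "cis"]), 1L)
  # the sulfotransferase is everywhere except cis
  expect_identical(unname(L["CHST4", ]), c(0L, 1L, 1L, 1L))
  # capping sialyltransferases live in the last two compartments
  for (e in c("ST3GAL", "ST6GAL1", "ST6GALNAC"))
    expect_identical(unname(L[e, ]), c(0L, 0L, 1L, 1L))
  # every enzyme is somewhere
  expect_true(all(rowSums(L) >= 1L))
})

test_that("profile comparison reports residuals over the union of structures", {
  a <- c("Galβ1-3GalNAcol" = 60, "NeuAcα2-3Galβ1-3GalNAcol" = 40)
  same <- compare_profiles(a, a)
  expect_equal(same$ssr, 0)
  expect_equal(same$max_abs_residual, 0)

  cmp <- compare_profiles(c("Galb1-3GalNAcol" = 100),
                          c("GlcNAcb1-3GalNAcol" = 100))
  expect_equal(cmp$ssr, 20000)
  tab <- cmp$table
  expect_equal(tab$residual[tab$structure == "Galβ1-3GalNAcol"], 100)
  expect_equal(tab$residual[tab$structure == "GlcNAcβ1-3GalNAcol"], -100)

  # symmetry up to residual sign
  rev <- compare_profiles(c("GlcNAcb1-3GalNAcol" = 100),
                          c("Galb1-3GalNAcol" = 100))
  expect_equal(rev$ssr, cmp$ssr)
  expect_equal(sort(rev$table$residual), sort(-cmp$table$residual))
})

test_that("profiles round-trip through the JSON format", {
  p <- glycan_profile(c("Galb1-3GalNAcol", "NeuAca2-3Galb1-3GalNAcol"),
                      c(75, 25))
  f <- tempfile(fileext = ".json")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$value, p$value)
  expect_identical(q$structure, p$structure)
  expect_identical(attr(q, "kind"), "adjusted")
  unlink(f)
})
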