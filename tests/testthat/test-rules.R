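test_that("the bundled rule set has the published inventory", {
  rs <- default_ruleset()
  expect_identical(nrow(rs$enzymes), 20L)
  expect_identical(length(rs$rules), 30L)
  expect_identical(sum(rs$enzymes$transfected), 12L)
  # suffixed sub-rules of one enzyme share the enzyme field
  ids <- names(rs$rules)
  suffixed <- grep("_[a-d]$", ids, value = TRUE)
  for (id in suffixed)
    expect_identical(rs$rules[[id]]$enzyme, sub("_[a-d]$", "", id))
  # every rule's enzyme exists in the enzyme table
  expect_true(all(vapply(rs$rules, function(r) r$enzyme, "") %in%
                    rs$enzymes$enzyme))
})

test_that("acceptor matching respects patterns and occupancy", {
  rs <- default_ruleset()
  tn <- parse_glycan("GalNAcol")
  core1 <- parse_glycan("Galb1-3GalNAcol")

  expect_length(match_sites(rs$rules$C1GALT1, tn), 1L)
  expect_identical(match_sites(rs$rules$C1GALT1, tn)[[1]], integer(0))
  # position 3 occupied: core 1 cannot be galactosylated again
  expect_length(match_sites(rs$rules$C1GALT1, core1), 0L)
  # B3GNT6 competes for the same Tn acceptor
  expect_length(match_sites(rs$rules$B3GNT6, tn), 1L)
  # core-2 branching requires the core-1 galactose
  expect_length(match_sites(rs$rules$GCNT1_a, tn), 0L)
  expect_length(match_sites(rs$rules$GCNT1_a, core1), 1L)
  # sialyl-Tn rule needs a bare root
  expect_length(match_sites(rs$rules$ST6GALNAC_a, core1), 0L)
  # FUT7 needs the sialylated type-2 arm, FUT4 the neutral one
  neutral <- parse_glycan("Galb1-4GlcNAcb1-3GalNAcol")
  sialyl <- parse_glycan("NeuAca2-3Galb1-4GlcNAcb1-3GalNAcol")
  expect_length(match_sites(rs$rules$FUT4, neutral), 1L)
  expect_length(match_sites(rs$rules$FUT4, sialyl), 0L)
  expect_length(match_sites(rs$rules$FUT7, neutral), 0L)
  expect_length(match_sites(rs$rules$FUT7, sialyl), 1L)
})

test_that("applying rules yields the canonical pathway products", {
  rs <- default_ruleset()
  tn <- parse_glycan("GalNAcol")
  core1 <- apply_rule(rs$rules$C1GALT1, tn, integer(0))
  expect_identical(format(core1), "Galβ1-3GalNAcol")
  # input unmodified
  expect_identical(format(tn), "GalNAcol")

  core2 <- apply_rule(rs$rules$GCNT1_a, core1,
                      match_sites(rs$rules$GCNT1_a, core1)[[1]])
  expect_identical(format(core2), "Galβ1-3(GlcNAcβ1-6)GalNAcol")

  st6 <- apply_rule(rs$rules$ST6GALNAC_b, core1,
                    match_sites(rs$rules$ST6GALNAC_b, core1)[[1]])
  expect_identical(format(st6), "Galβ1-3(NeuAcα2-6)GalNAcol")

  # sulfation adds a substituent, not a residue
  core3 <- apply_rule(rs$rules$B3GNT6, tn, integer(0))
  sulf <- apply_rule(rs$rules$CHST4_a, core3,
                     match_sites(rs$rules$CHST4_a, core3)[[1]])
  expect_identical(format(sulf), "6SGlcNAcβ1-3GalNAcol")
  expect_identical(substituent_count(sulf), 1L)

  expect_error(apply_rule(rs$rules$C1GALT1, core1, integer(0)),
               "not a match")
})

test_that("every reaction conserves the acceptor backbone (+1 residue or substituent)", {
  rs <- default_ruleset()
  nets <- list(
    chowt_network(),
    build_network(rs, c("B3GNT6", "B4GALT", "ST3GAL_b", "FUT7", "CHST4_a",
                        "CHST4_b")),
    build_network(rs, c("C1GALT1", "GCNT1_a", "B3GALT5", "FUT2", "FUT3_a")))
  for (net in nets) {
    expect_gt(nrow(net$reactions), 0L)
    for (i in seq_len(nrow(net$reactions))) {
      sub <- parse_glycan(net$reactions$substrate[i])
      prod <- parse_glycan(net$reactions$product[i])
      if (net$reactions$enzyme[i] == "CHST4") {
        expect_identical(residue_count(prod), residue_count(sub))
        expect_identical(substituent_count(prod), substituent_count(sub) + 1L)
      } else {
        expect_identical(residue_count(prod), residue_count(sub) + 1L)
        expect_identical(substituent_count(prod), substituent_count(sub))
      }
    }
  }
})

test_that("parse(serialize(t)) is the identity on every generated species", {
  for (net in list(chowt_network(),
                   build_network(default_ruleset(),
                                 c("B3GNT6", "GCNT1_b", "B4GALT", "CHST4_a",
                                   "CHST4_b", "ST6GAL1")))) {
    for (s in net$species)
      expect_identical(format(parse_glycan(s)), s)
  }
})
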