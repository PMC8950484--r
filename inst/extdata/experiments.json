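{
  "comment": "25 transfection experiment configurations. 'transfected' follows the published experiment table; 'active_rule_ids' adds the minimal required (endogenous) rules so every structure of the bundled observed list is reachable. Observed structures are written in condensed IUPAC with ASCII anomer letters (a/b); they are canonicalized on load. The bundled observed profiles are SYNTHETIC stand-ins (the measured abundances were published only as figures): structure lists are curated from the experiment design, abundances are generated by generate_scenario().",
  "experiments": [
    {"name": "CHO/CHO-WT", "aliases": ["CHO-WT", "CHO"], "transfected": [],
     "active_rule_ids": ["C1GALT1", "ST3GAL_a", "ST6GALNAC_a", "ST6GALNAC_b", "ST6GALNAC_c"],
     "observed_structures": ["Galb1-3(NeuAca2-6)GalNAcol", "NeuAca2-3Galb1-3GalNAcol", "NeuAca2-3Galb1-3(NeuAca2-6)GalNAcol"]},

    {"name": "Leb on C2", "transfected": ["GCNT1", "B3GALT5", "FUT2", "FUT4"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B3GALT5", "FUT2", "FUT3_a", "FUT4"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-3GlcNAcb1-6)GalNAcol", "Galb1-3(Fuca1-2Galb1-3GlcNAcb1-6)GalNAcol", "Galb1-3(Fuca1-2Galb1-3(Fuca1-4)GlcNAcb1-6)GalNAcol"]},

    {"name": "Leb on C3", "transfected": ["B3GNT6", "B3GALT5", "FUT2", "FUT4"],
     "active_rule_ids": ["B3GNT6", "B3GALT5", "FUT2", "FUT3_a", "FUT4"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "Galb1-3GlcNAcb1-3GalNAcol", "Fuca1-2Galb1-3GlcNAcb1-3GalNAcol", "Fuca1-2Galb1-3(Fuca1-4)GlcNAcb1-3GalNAcol"]},

    {"name": "Leb on exC1", "transfected": ["B3GNT3", "B3GALT5", "FUT2", "FUT4"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B3GALT5", "FUT2", "FUT3_a", "FUT4"],
     "observed_structures": ["Galb1-3GalNAcol", "GlcNAcb1-3Galb1-3GalNAcol", "Galb1-3GlcNAcb1-3Galb1-3GalNAcol", "Fuca1-2Galb1-3(Fuca1-4)GlcNAcb1-3Galb1-3GalNAcol"]},

    {"name": "Slex on C2", "transfected": ["GCNT1", "FUT7"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALT", "ST3GAL_b", "FUT7"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(NeuAca2-3Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(NeuAca2-3Galb1-4(Fuca1-3)GlcNAcb1-6)GalNAcol"]},

    {"name": "Slex on C3", "transfected": ["B3GNT6", "FUT7"],
     "active_rule_ids": ["B3GNT6", "B4GALT", "ST3GAL_b", "FUT7"],
     "observed_structures": ["Galb1-4GlcNAcb1-3GalNAcol", "NeuAca2-3Galb1-4GlcNAcb1-3GalNAcol", "NeuAca2-3Galb1-4(Fuca1-3)GlcNAcb1-3GalNAcol"]},

    {"name": "Slex on exC1", "transfected": ["B3GNT3", "FUT7"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B3GNT6", "B4GALT", "ST3GAL_b", "FUT7"],
     "observed_structures": ["Galb1-3GalNAcol", "Galb1-4GlcNAcb1-3GalNAcol", "Galb1-4GlcNAcb1-3Galb1-3GalNAcol", "NeuAca2-3Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-3GalNAcol"]},

    {"name": "A4GlcNAc on C1", "transfected": ["A4GNT"],
     "active_rule_ids": ["C1GALT1", "A4GNT", "ST3GAL_a"],
     "observed_structures": ["Galb1-3GalNAcol", "GlcNAca1-4Galb1-3GalNAcol", "NeuAca2-3Galb1-3GalNAcol"]},

    {"name": "LacdiNAc on C2", "transfected": ["GCNT1", "B4GALNT3"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALNT3"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(GalNAcb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "A4GlcNAc and LacdiNAc on C2", "transfected": ["GCNT1", "A4GNT", "B4GALNT3"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "A4GNT", "B4GALNT3"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(GalNAcb1-4GlcNAcb1-6)GalNAcol", "GlcNAca1-4Galb1-3(GlcNAcb1-6)GalNAcol"]},

    {"name": "α1,3Gal on C2", "transfected": ["GCNT1", "A3GALT"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALT", "A3GALT"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(Gala1-3Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "α1,4Gal on C2", "transfected": ["GCNT1", "A4GALT"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALT", "A4GALT"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(Gala1-4Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "ExC1", "transfected": ["B3GNT3"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B4GALT", "ST3GAL_b"],
     "observed_structures": ["Galb1-3GalNAcol", "GlcNAcb1-3Galb1-3GalNAcol", "Galb1-4GlcNAcb1-3Galb1-3GalNAcol", "NeuAca2-3Galb1-4GlcNAcb1-3Galb1-3GalNAcol"]},

    {"name": "C2", "transfected": ["GCNT1"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALT", "ST3GAL_b"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(NeuAca2-3Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "Terminal type 1 on C3", "transfected": ["B3GNT6", "B3GALT5"],
     "active_rule_ids": ["B3GNT6", "B3GALT5", "ST3GAL_a"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "Galb1-3GlcNAcb1-3GalNAcol", "NeuAca2-3Galb1-3GlcNAcb1-3GalNAcol"]},

    {"name": "Terminal type 2 on C3", "transfected": ["B3GNT6"],
     "active_rule_ids": ["B3GNT6", "B4GALT", "ST3GAL_b"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "Galb1-4GlcNAcb1-3GalNAcol", "NeuAca2-3Galb1-4GlcNAcb1-3GalNAcol"]},

    {"name": "Terminal type 1 on C4", "transfected": ["GCNT1", "B3GNT6", "B3GALT5"],
     "active_rule_ids": ["B3GNT6", "GCNT1_b", "B3GALT5"],
     "observed_structures": ["GlcNAcb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3GlcNAcb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3GlcNAcb1-3(Galb1-3GlcNAcb1-6)GalNAcol"]},

    {"name": "C4", "transfected": ["GCNT1", "B3GNT6"],
     "active_rule_ids": ["B3GNT6", "GCNT1_b", "B4GALT"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "GlcNAcb1-3(GlcNAcb1-6)GalNAcol", "Galb1-4GlcNAcb1-3(Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "α2,6sialic acid", "transfected": ["ST6GAL1"],
     "active_rule_ids": ["C1GALT1", "ST6GALNAC_b", "B3GNT3", "B4GALT", "ST6GAL1"],
     "observed_structures": ["Galb1-3(NeuAca2-6)GalNAcol", "Galb1-4GlcNAcb1-3Galb1-3GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3Galb1-3GalNAcol"]},

    {"name": "α2,6sialic acid with type 1 on exC1", "transfected": ["ST6GAL1", "B3GNT3"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B3GALT5", "B4GALT", "ST6GAL1"],
     "observed_structures": ["GlcNAcb1-3Galb1-3GalNAcol", "Galb1-3GlcNAcb1-3Galb1-3GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3Galb1-3GalNAcol"]},

    {"name": "α2,6sialic acid on C2", "transfected": ["ST6GAL1", "GCNT1"],
     "active_rule_ids": ["C1GALT1", "GCNT1_a", "B4GALT", "ST6GAL1"],
     "observed_structures": ["Galb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "Galb1-3(NeuAca2-6Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "α2,6sialic acid with type 1 on C3", "transfected": ["ST6GAL1", "B3GNT6", "B3GALT5"],
     "active_rule_ids": ["B3GNT6", "B3GALT5", "B4GALT", "ST6GAL1"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "Galb1-3GlcNAcb1-3GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3GalNAcol"]},

    {"name": "α2,6sialic acid on C3", "transfected": ["ST6GAL1", "B3GNT6"],
     "active_rule_ids": ["B3GNT6", "B4GALT", "ST6GAL1"],
     "observed_structures": ["GlcNAcb1-3GalNAcol", "Galb1-4GlcNAcb1-3GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3GalNAcol"]},

    {"name": "α2,6sialic acid with type 1 on C4", "transfected": ["ST6GAL1", "B3GNT3", "GCNT1", "B3GALT5"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B3GNT6", "GCNT1_b", "B3GALT5", "B4GALT", "ST6GAL1"],
     "observed_structures": ["GlcNAcb1-3(GlcNAcb1-6)GalNAcol", "Galb1-3GlcNAcb1-3(Galb1-3GlcNAcb1-6)GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3(Galb1-4GlcNAcb1-6)GalNAcol"]},

    {"name": "α2,6sialic acid on C4", "transfected": ["ST6GAL1", "B3GNT3", "GCNT1"],
     "active_rule_ids": ["C1GALT1", "B3GNT3", "B3GNT6", "GCNT1_b", "B4GALT", "ST6GAL1"],
     "observed_structures": ["GlcNAcb1-3(GlcNAcb1-6)GalNAcol", "Galb1-4GlcNAcb1-3(Galb1-4GlcNAcb1-6)GalNAcol", "NeuAca2-6Galb1-4GlcNAcb1-3(Galb1-4GlcNAcb1-6)GalNAcol"]}
  ]
}
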