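{
  "comment": "Four-compartment Golgi configuration: donor-sugar concentrations (uM) per compartment and binary enzyme localization. Donors are clamped constants and are zero in compartments where the corresponding sugar is not donated; enzyme localization follows the catalytic role (core synthesis in cis, branching in medial, elongation/capping in trans/TGN, fucosylation in medial/trans, sulfation everywhere but cis).",
  "compartments": ["cis", "medial", "trans", "TGN"],
  "residence_time_min": 5.56,
  "volume_uL": 2.5,
  "initial_root_concentration": 100,
  "glycan_unit": "umol/uL",
  "donors": {
    "CMP_NeuAc":  [0, 0, 3000, 3000],
    "CMP_NeuGc":  [0, 0, 3000, 3000],
    "GDP_Fuc":    [0, 5000, 5000, 0],
    "UDP_GlcNAc": [9143, 9143, 9143, 0],
    "UDP_Gal":    [3810, 0, 3810, 3810],
    "UDP_GalNAc": [0, 0, 3000, 0],
    "PAP_S":      [0, 920, 920, 920]
  },
  "localization": {
    "C1GALT1":   [1, 0, 0, 0],
    "B3GNT6":    [1, 0, 0, 0],
    "GCNT1":     [0, 1, 0, 0],
    "GCNT3":     [0, 1, 0, 0],
    "FUT2":      [0, 1, 1, 0],
    "FUT3":      [0, 1, 1, 0],
    "FUT4":      [0, 1, 1, 0],
    "FUT7":      [0, 1, 1, 0],
    "CHST4":     [0, 1, 1, 1],
    "B3GNT":     [0, 0, 1, 0],
    "B3GNT3":    [0, 0, 1, 0],
    "A4GNT":     [0, 0, 1, 0],
    "B4GALNT3":  [0, 0, 1, 0],
    "B4GALT":    [0, 0, 1, 1],
    "B3GALT5":   [0, 0, 1, 1],
    "A3GALT":    [0, 0, 1, 1],
    "A4GALT":    [0, 0, 1, 1],
    "ST3GAL":    [0, 0, 1, 1],
    "ST6GAL1":   [0, 0, 1, 1],
    "ST6GALNAC": [0, 0, 1, 1]
  }
}
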