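[
  {
    "label": "r1_ring_closure (2 monomer -> cyc_2 + 2 H2O)",
    "stoichiometry": {
      "monomer": -2,
      "cyc_2": 1,
      "h2o": 2
    }
  },
  {
    "label": "r1_insertion_n2 (cyc_2 + monomer -> cyc_3 + H2O)",
    "stoichiometry": {
      "cyc_2": -1,
      "monomer": -1,
      "cyc_3": 1,
      "h2o": 1
    }
  },
  {
    "label": "r1_insertion_n3 (cyc_3 + monomer -> cyc_4 + H2O)",
    "stoichiometry": {
      "cyc_3": -1,
      "monomer": -1,
      "cyc_4": 1,
      "h2o": 1
    }
  },
  {
    "label": "r2 (H3PO4 + H2SO4 -> monomer + H2O)",
    "stoichiometry": {
      "h3po4": -1,
      "h2so4": -1,
      "monomer": 1,
      "h2o": 1
    }
  },
  {
    "label": "r3 (H3PO4 + SO3 -> monomer)",
    "stoichiometry": {
      "h3po4": -1,
      "so3": -1,
      "monomer": 1
    }
  },
  {
    "label": "r4 (HPO3 + H2SO4 -> monomer)",
    "stoichiometry": {
      "hpo3": -1,
      "h2so4": -1,
      "monomer": 1
    }
  },
  {
    "label": "r5 (4 H3PO4 + 4 SO3 -> cyc_4 + 4 H2O)",
    "stoichiometry": {
      "h3po4": -4,
      "so3": -4,
      "cyc_4": 1,
      "h2o": 4
    }
  },
  {
    "label": "r6 (4 HPO3 + 4 H2SO4 -> cyc_4 + 4 H2O)",
    "stoichiometry": {
      "hpo3": -4,
      "h2so4": -4,
      "cyc_4": 1,
      "h2o": 4
    }
  },
  {
    "label": "r7 (4 monomer -> cyc_4 + 4 H2O)",
    "stoichiometry": {
      "monomer": -4,
      "cyc_4": 1,
      "h2o": 4
    }
  },
  {
    "label": "r8 (SO3 + H2O -> H2SO4)",
    "stoichiometry": {
      "so3": -1,
      "h2o": -1,
      "h2so4": 1
    }
  },
  {
    "label": "r9 (HPO3 + H2O -> H3PO4)",
    "stoichiometry": {
      "hpo3": -1,
      "h2o": -1,
      "h3po4": 1
    }
  },
  {
    "label": "r10 (cyc_4 + H2O -> linear tetramer)",
    "stoichiometry": {
      "cyc_4": -1,
      "h2o": -1,
      "linear_tetramer": 1
    }
  }
]
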