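{
  "id": "mini_core_synthetic",
  "metabolites": [
    {"id": "glc__D_e", "name": "D-glucose", "compartment": "e"},
    {"id": "glc__D_c", "name": "D-glucose", "compartment": "c"},
    {"id": "pyr_c", "name": "pyruvate", "compartment": "c"},
    {"id": "lac__L_c", "name": "L-lactate", "compartment": "c"},
    {"id": "lac__L_e", "name": "L-lactate", "compartment": "e"}
  ],
  "reactions": [
    {"id": "EX_glc__D_e", "metabolites": {"glc__D_e": -1.0},
     "lower_bound": -10.0, "upper_bound": 0.0, "gene_reaction_rule": "",
     "subsystem": "exchange", "objective_coefficient": 0},
    {"id": "GLCt1", "metabolites": {"glc__D_e": -1.0, "glc__D_c": 1.0},
     "lower_bound": 0.0, "upper_bound": 1000.0, "gene_reaction_rule": "SLC2A1",
     "subsystem": "transport", "objective_coefficient": 0},
    {"id": "GLYCL", "metabolites": {"glc__D_c": -1.0, "pyr_c": 2.0},
     "lower_bound": 0.0, "upper_bound": 1000.0,
     "gene_reaction_rule": "HK1 and PKM", "subsystem": "glycolysis",
     "objective_coefficient": 0},
    {"id": "LDH_L", "metabolites": {"pyr_c": -1.0, "lac__L_c": 1.0},
     "lower_bound": -1000.0, "upper_bound": 1000.0,
     "gene_reaction_rule": "LDHA or LDHB", "subsystem": "fermentation",
     "objective_coefficient": 0},
    {"id": "L_LACt", "metabolites": {"lac__L_c": -1.0, "lac__L_e": 1.0},
     "lower_bound": 0.0, "upper_bound": 1000.0, "gene_reaction_rule": "",
     "subsystem": "transport", "objective_coefficient": 0},
    {"id": "EX_lac__L_e", "metabolites": {"lac__L_e": -1.0},
     "lower_bound": 0.0, "upper_bound": 1000.0, "gene_reaction_rule": "",
     "subsystem": "exchange", "objective_coefficient": 1.0}
  ]
}
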