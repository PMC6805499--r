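{
  "id": "mini_aerobe",
  "metabolites": [
    {"id": "glc_e", "name": "D-glucose", "compartment": "e", "formula": "C6"},
    {"id": "o2_e", "name": "oxygen", "compartment": "e", "formula": "O2"},
    {"id": "o2", "name": "oxygen", "compartment": "c", "formula": "O2"},
    {"id": "x", "name": "carbon unit", "compartment": "c", "formula": "C3"},
    {"id": "atp", "name": "ATP", "compartment": "c", "formula": "P1"},
    {"id": "prec", "name": "precursor", "compartment": "c", "formula": "C3"}
  ],
  "reactions": [
    {"id": "EX_glc", "name": "glucose exchange", "stoich": {"glc_e": -1}, "lb": -10, "ub": 0},
    {"id": "EX_o2", "name": "oxygen exchange", "stoich": {"o2_e": -1}, "lb": -20, "ub": 0},
    {"id": "O2t", "name": "oxygen transport", "stoich": {"o2_e": -1, "o2": 1}, "lb": 0, "ub": 1000},
    {"id": "CATAB", "name": "catabolic lump", "stoich": {"glc_e": -1, "x": 2}, "lb": 0, "ub": 1000},
    {"id": "RESP", "name": "respiratory ATP", "stoich": {"x": -1, "o2": -1, "atp": 2}, "lb": 0, "ub": 1000},
    {"id": "SYNTH_O2", "name": "O2-dependent precursor synthesis", "stoich": {"x": -1, "o2": -0.5, "prec": 1}, "lb": 0, "ub": 1000},
    {"id": "ATPM", "name": "maintenance", "stoich": {"atp": -1}, "lb": 1, "ub": 1000},
    {"id": "BIOMASS", "name": "biomass", "stoich": {"prec": -1, "atp": -2}, "lb": 0, "ub": 1000}
  ],
  "objective": "BIOMASS",
  "o2_metabolites": ["o2_e", "o2"]
}
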