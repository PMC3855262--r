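{
  "id": "toy",
  "metabolites": [
    {"id": "A_c", "name": "metabolite A", "compartment": "c"},
    {"id": "B_c", "name": "metabolite B", "compartment": "c"},
    {"id": "C_c", "name": "metabolite C", "compartment": "c"},
    {"id": "D_c", "name": "metabolite D", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "EX_A",
      "name": "A exchange",
      "metabolites": {"A_c": -1},
      "lower_bound": -10,
      "upper_bound": 1000,
      "gene_reaction_rule": ""
    },
    {
      "id": "R1",
      "name": "A to B",
      "metabolites": {"A_c": -1, "B_c": 1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g1"
    },
    {
      "id": "R2",
      "name": "B to C",
      "metabolites": {"B_c": -1, "C_c": 1},
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "g2 or g3"
    },
    {
      "id": "R3",
      "name": "B and C to D",
      "metabolites": {"B_c": -1, "C_c": -1, "D_c": 2},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g2 and g3"
    },
    {
      "id": "BIOMASS_toy",
      "name": "toy biomass",
      "metabolites": {"C_c": -0.5, "D_c": -1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": ""
    }
  ],
  "genes": [
    {"id": "g1", "name": "g1"},
    {"id": "g2", "name": "g2"},
    {"id": "g3", "name": "g3"}
  ]
}
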