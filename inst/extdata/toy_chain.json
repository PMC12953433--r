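{
  "metabolites": [
    {
      "id": "A",
      "name": "metabolite A",
      "compartment": "c"
    },
    {
      "id": "A_ext",
      "name": "A (medium)",
      "compartment": "e"
    },
    {
      "id": "B",
      "name": "metabolite B",
      "compartment": "c"
    },
    {
      "id": "B_ext",
      "name": "B (medium)",
      "compartment": "e"
    }
  ],
  "external": ["A_ext", "B_ext"],
  "reactions": [
    {
      "id": "r_AtoB",
      "reversible": false,
      "stoichiometry": {
        "A": -1,
        "B": 1
      },
      "protein_ids": [
        ["gene1", "gene2"],
        "gene3"
      ]
    },
    {
      "id": "r_Auptake",
      "reversible": false,
      "stoichiometry": {
        "A": 1,
        "A_ext": -1
      },
      "protein_ids": []
    },
    {
      "id": "r_Bexport",
      "reversible": false,
      "stoichiometry": {
        "B": -1,
        "B_ext": 1
      },
      "protein_ids": [
        "gene4"
      ]
    }
  ],
  "target_reaction": "r_Bexport"
}
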