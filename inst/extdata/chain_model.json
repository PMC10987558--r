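{
  "taxon_id": "chain",
  "metabolites": [
    {
      "id": "A_e",
      "compartment": "extracellular"
    },
    {
      "id": "B_e",
      "compartment": "extracellular"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "stoich": {
        "A_e": -1
      },
      "lb": -10,
      "ub": 0,
      "exchange": true,
      "objective": 0
    },
    {
      "id": "CONV",
      "stoich": {
        "A_e": -1,
        "B_e": 1
      },
      "lb": 0,
      "ub": 1000,
      "exchange": false,
      "objective": 0
    },
    {
      "id": "EX_B",
      "stoich": {
        "B_e": -1
      },
      "lb": 0,
      "ub": 1000,
      "exchange": true,
      "objective": 1
    }
  ]
}
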