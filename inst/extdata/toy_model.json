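{
  "metabolites": [
    {
      "id": "A_ext",
      "name": "A_ext",
      "is_internal": false,
      "formula": "C3H6O3"
    },
    {
      "id": "D_ext",
      "name": "D_ext",
      "is_internal": false,
      "formula": "C3H6O3"
    },
    {
      "id": "F_ext",
      "name": "F_ext",
      "is_internal": false,
      "formula": "C3H6O3"
    },
    {
      "id": "A",
      "name": "A",
      "is_internal": true,
      "formula": "C3H6O3"
    },
    {
      "id": "B",
      "name": "B",
      "is_internal": true,
      "formula": "C3H6O3"
    },
    {
      "id": "C",
      "name": "C",
      "is_internal": true,
      "formula": "C3H6O3"
    },
    {
      "id": "D",
      "name": "D",
      "is_internal": true,
      "formula": "C3H6O3"
    },
    {
      "id": "E",
      "name": "E",
      "is_internal": true,
      "formula": "C3H6O3"
    },
    {
      "id": "F",
      "name": "F",
      "is_internal": true,
      "formula": "C3H6O3"
    }
  ],
  "reactions": [
    {
      "id": "r1",
      "stoichiometry": {
        "A_ext": -1,
        "A": 1
      },
      "reversible": false
    },
    {
      "id": "r2",
      "stoichiometry": {
        "A": -1,
        "B": 1
      },
      "reversible": false
    },
    {
      "id": "r3",
      "stoichiometry": {
        "B": -1,
        "C": 1
      },
      "reversible": false
    },
    {
      "id": "r4",
      "stoichiometry": {
        "C": -1,
        "D": -1,
        "E": 1
      },
      "reversible": false
    },
    {
      "id": "r5",
      "stoichiometry": {
        "E": -1,
        "F": 1
      },
      "reversible": false
    },
    {
      "id": "r6",
      "stoichiometry": {
        "D_ext": -1,
        "D": 1
      },
      "reversible": false
    },
    {
      "id": "r7",
      "stoichiometry": {
        "F": -1,
        "F_ext": 1
      },
      "reversible": false
    }
  ]
}
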