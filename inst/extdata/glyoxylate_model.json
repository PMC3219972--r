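{
  "metabolites": [
    {
      "id": "AcCoA",
      "name": "AcCoA",
      "is_internal": true
    },
    {
      "id": "Cit",
      "name": "Cit",
      "is_internal": true
    },
    {
      "id": "ICit",
      "name": "ICit",
      "is_internal": true
    },
    {
      "id": "AKG",
      "name": "AKG",
      "is_internal": true
    },
    {
      "id": "SUCCoA",
      "name": "SUCCoA",
      "is_internal": true
    },
    {
      "id": "SUCC",
      "name": "SUCC",
      "is_internal": true
    },
    {
      "id": "Fum",
      "name": "Fum",
      "is_internal": true
    },
    {
      "id": "L-Mal",
      "name": "L-Mal",
      "is_internal": true
    },
    {
      "id": "OAA",
      "name": "OAA",
      "is_internal": true
    },
    {
      "id": "Glx",
      "name": "Glx",
      "is_internal": true
    },
    {
      "id": "Pyr",
      "name": "Pyr",
      "is_internal": true
    },
    {
      "id": "PEP",
      "name": "PEP",
      "is_internal": true
    },
    {
      "id": "G6P",
      "name": "G6P",
      "is_internal": true
    },
    {
      "id": "D-Glc",
      "name": "D-Glc",
      "is_internal": true
    },
    {
      "id": "CO2",
      "name": "CO2",
      "is_internal": true
    },
    {
      "id": "CoA",
      "name": "CoA",
      "is_internal": true
    },
    {
      "id": "NAD",
      "name": "NAD",
      "is_internal": true
    },
    {
      "id": "NADH",
      "name": "NADH",
      "is_internal": true
    },
    {
      "id": "ATP",
      "name": "ATP",
      "is_internal": true
    },
    {
      "id": "ADP",
      "name": "ADP",
      "is_internal": true
    },
    {
      "id": "Pi",
      "name": "Pi",
      "is_internal": true
    },
    {
      "id": "CoQ",
      "name": "CoQ",
      "is_internal": true
    },
    {
      "id": "CoQH2",
      "name": "CoQH2",
      "is_internal": true
    },
    {
      "id": "FA_ext",
      "name": "FA_ext",
      "is_internal": false
    },
    {
      "id": "D-Glc_ext",
      "name": "D-Glc_ext",
      "is_internal": false
    },
    {
      "id": "CO2_ext",
      "name": "CO2_ext",
      "is_internal": false
    },
    {
      "id": "O2_ext",
      "name": "O2_ext",
      "is_internal": false
    },
    {
      "id": "Pi_ext",
      "name": "Pi_ext",
      "is_internal": false
    }
  ],
  "reactions": [
    {
      "id": "FAUP",
      "stoichiometry": {
        "FA_ext": -1,
        "CoA": -1,
        "AcCoA": 1
      },
      "reversible": false
    },
    {
      "id": "CS",
      "stoichiometry": {
        "AcCoA": -1,
        "OAA": -1,
        "Cit": 1,
        "CoA": 1
      },
      "reversible": false
    },
    {
      "id": "ACONT__fwd",
      "stoichiometry": {
        "Cit": -1,
        "ICit": 1
      },
      "reversible": false,
      "reverse_of": "ACONT__rev"
    },
    {
      "id": "ACONT__rev",
      "stoichiometry": {
        "Cit": 1,
        "ICit": -1
      },
      "reversible": false,
      "reverse_of": "ACONT__fwd"
    },
    {
      "id": "ICDHyr",
      "stoichiometry": {
        "ICit": -1,
        "NAD": -1,
        "AKG": 1,
        "CO2": 1,
        "NADH": 1
      },
      "reversible": false
    },
    {
      "id": "AKGDH",
      "stoichiometry": {
        "AKG": -1,
        "CoA": -1,
        "NAD": -1,
        "SUCCoA": 1,
        "CO2": 1,
        "NADH": 1
      },
      "reversible": false
    },
    {
      "id": "SUCOAS__fwd",
      "stoichiometry": {
        "SUCCoA": -1,
        "ADP": -1,
        "Pi": -1,
        "SUCC": 1,
        "CoA": 1,
        "ATP": 1
      },
      "reversible": false,
      "reverse_of": "SUCOAS__rev"
    },
    {
      "id": "SUCOAS__rev",
      "stoichiometry": {
        "SUCCoA": 1,
        "ADP": 1,
        "Pi": 1,
        "SUCC": -1,
        "CoA": -1,
        "ATP": -1
      },
      "reversible": false,
      "reverse_of": "SUCOAS__fwd"
    },
    {
      "id": "SUCDi",
      "stoichiometry": {
        "SUCC": -1,
        "CoQ": -1,
        "Fum": 1,
        "CoQH2": 1
      },
      "reversible": false
    },
    {
      "id": "FUM__fwd",
      "stoichiometry": {
        "Fum": -1,
        "L-Mal": 1
      },
      "reversible": false,
      "reverse_of": "FUM__rev"
    },
    {
      "id": "FUM__rev",
      "stoichiometry": {
        "Fum": 1,
        "L-Mal": -1
      },
      "reversible": false,
      "reverse_of": "FUM__fwd"
    },
    {
      "id": "MDH__fwd",
      "stoichiometry": {
        "L-Mal": -1,
        "NAD": -1,
        "OAA": 1,
        "NADH": 1
      },
      "reversible": false,
      "reverse_of": "MDH__rev"
    },
    {
      "id": "MDH__rev",
      "stoichiometry": {
        "L-Mal": 1,
        "NAD": 1,
        "OAA": -1,
        "NADH": -1
      },
      "reversible": false,
      "reverse_of": "MDH__fwd"
    },
    {
      "id": "PDH",
      "stoichiometry": {
        "Pyr": -1,
        "CoA": -1,
        "NAD": -1,
        "AcCoA": 1,
        "CO2": 1,
        "NADH": 1
      },
      "reversible": false
    },
    {
      "id": "PYK",
      "stoichiometry": {
        "PEP": -1,
        "ADP": -1,
        "Pyr": 1,
        "ATP": 1
      },
      "reversible": false
    },
    {
      "id": "PC",
      "stoichiometry": {
        "Pyr": -1,
        "CO2": -1,
        "ATP": -1,
        "OAA": 1,
        "ADP": 1,
        "Pi": 1
      },
      "reversible": false
    },
    {
      "id": "PCK1",
      "stoichiometry": {
        "OAA": -1,
        "ATP": -1,
        "PEP": 1,
        "CO2": 1,
        "ADP": 1
      },
      "reversible": false
    },
    {
      "id": "ME1",
      "stoichiometry": {
        "L-Mal": -1,
        "NAD": -1,
        "Pyr": 1,
        "CO2": 1,
        "NADH": 1
      },
      "reversible": false
    },
    {
      "id": "GNG",
      "stoichiometry": {
        "PEP": -2,
        "ATP": -2,
        "NADH": -2,
        "G6P": 1,
        "ADP": 2,
        "NAD": 2,
        "Pi": 1
      },
      "reversible": false
    },
    {
      "id": "G6PP",
      "stoichiometry": {
        "G6P": -1,
        "D-Glc": 1,
        "Pi": 1
      },
      "reversible": false
    },
    {
      "id": "GLCex",
      "stoichiometry": {
        "D-Glc": -1,
        "D-Glc_ext": 1
      },
      "reversible": false
    },
    {
      "id": "NADHOX",
      "stoichiometry": {
        "NADH": -1,
        "O2_ext": -0.5,
        "NAD": 1
      },
      "reversible": false
    },
    {
      "id": "CoQOX",
      "stoichiometry": {
        "CoQH2": -1,
        "O2_ext": -0.5,
        "CoQ": 1
      },
      "reversible": false
    },
    {
      "id": "ATPM__fwd",
      "stoichiometry": {
        "ATP": -1,
        "ADP": 1,
        "Pi": 1
      },
      "reversible": false,
      "reverse_of": "ATPM__rev"
    },
    {
      "id": "ATPM__rev",
      "stoichiometry": {
        "ATP": 1,
        "ADP": -1,
        "Pi": -1
      },
      "reversible": false,
      "reverse_of": "ATPM__fwd"
    },
    {
      "id": "PIt",
      "stoichiometry": {
        "Pi_ext": -1,
        "Pi": 1
      },
      "reversible": false
    },
    {
      "id": "CO2t",
      "stoichiometry": {
        "CO2": -1,
        "CO2_ext": 1
      },
      "reversible": false
    },
    {
      "id": "ICL",
      "stoichiometry": {
        "ICit": -1,
        "SUCC": 1,
        "Glx": 1
      },
      "reversible": false
    },
    {
      "id": "MALS",
      "stoichiometry": {
        "AcCoA": -1,
        "Glx": -1,
        "L-Mal": 1,
        "CoA": 1
      },
      "reversible": false
    }
  ]
}
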