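[
  {
    "name": "dsxRE",
    "iupac": "TCWWCAATCAACA",
    "class": "activator",
    "source": "Drosophila dsx repeat element (TRA/TRA-2 binding site), TC(T/A)(T/A)CAATCAACA"
  },
  {
    "name": "NvdsxRE",
    "iupac": "KGAAGATW",
    "class": "activator",
    "source": "Nasonia/Apis dsx repeat element, (T/G)GAAGAT(T/A)"
  },
  {
    "name": "RBP1_A",
    "iupac": "DCADCTTTA",
    "class": "activator",
    "source": "RBP1 binding site, type A"
  },
  {
    "name": "RBP1_B",
    "iupac": "ATCYNNA",
    "class": "activator",
    "source": "RBP1 binding site, type B"
  },
  {
    "name": "TRA2_ISS",
    "iupac": "CAAGR",
    "class": "silencer",
    "source": "TRA-2 intronic splicing silencer"
  }
]
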