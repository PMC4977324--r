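{
  "priors": {
    "Sample": [0.5, 0.5],
    "TCF4": [0.1, 0.9],
    "MeDACT1": [0.837, 0.163],
    "MeDACT2": [0.3376, 0.6624],
    "MeWIF1": [0.1667, 0.8333],
    "MeSFRP1": [0.6316, 0.3684],
    "MeSFRP2": [0.6316, 0.3684],
    "MeSFRP4": [0.8572, 0.1428],
    "MeSFRP5": [0.75, 0.25],
    "H3K27me3": [0.2391, 0.7609],
    "H3K4me3": [0.3661, 0.6339],
    "MeDKK1": [0.5, 0.5],
    "MeDKK4": [0.5, 0.5],
    "BETACAT": [0.5, 0.5]
  },
  "tables": {
    "DVL2": {
      "parents": ["DACT3"],
      "off": [0.01, 0.99],
      "on": [0.99, 0.01]
    },
    "BETACAT": {
      "parents": ["DACT1", "DVL2"],
      "off": [0.99, 0.99, 0.99, 0.01],
      "on": [0.01, 0.01, 0.01, 0.99]
    },
    "TRCMPLX": {
      "parents": ["TCF4", "LEF1", "BETACAT"],
      "off": [0.99, 0.99, 0.99, 0.99, 0.99, 0.99, 0.99, 0.01],
      "on": [0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.99]
    },
    "LEF1": {
      "parents": ["Sample"],
      "off": [0.84, 0.16],
      "on": [0.16, 0.84]
    },
    "MYC": {
      "parents": ["Sample", "TRCMPLX"],
      "off": [0.94, 0.89, 0.78, 0.31],
      "on": [0.06, 0.11, 0.22, 0.69]
    },
    "CCND1": {
      "parents": ["Sample", "TRCMPLX"],
      "off": [0.95, 0.89, 0.81, 0.28],
      "on": [0.06, 0.11, 0.18, 0.72]
    },
    "CD44": {
      "parents": ["Sample", "TRCMPLX"],
      "off": [0.93, 0.9, 0.67, 0.42],
      "on": [0.07, 0.1, 0.33, 0.58]
    },
    "DKK1": {
      "parents": ["Sample", "MeDKK1", "TRCMPLX"],
      "off": [0.95, 0.93, 0.07, 0.05, 0.77, 0.6, 0.4, 0.23],
      "on": [0.05, 0.07, 0.93, 0.95, 0.23, 0.4, 0.6, 0.76]
    },
    "DKK2": {
      "parents": ["Sample"],
      "off": [0.4, 0.6],
      "on": [0.6, 0.4]
    },
    "DKK3-1": {
      "parents": ["Sample"],
      "off": [0.36, 0.64],
      "on": [0.64, 0.36]
    },
    "DKK3-2": {
      "parents": ["Sample"],
      "off": [0.56, 0.44],
      "on": [0.44, 0.56]
    },
    "DKK4": {
      "parents": ["Sample", "TRCMPLX"],
      "off": [0.94, 0.88, 0.82, 0.28],
      "on": [0.06, 0.11, 0.18, 0.72]
    },
    "DACT1": {
      "parents": ["Sample", "MeDACT1"],
      "off": [0.56, 0.74, 0.26, 0.44],
      "on": [0.44, 0.26, 0.74, 0.56]
    },
    "DACT2": {
      "parents": ["Sample", "MeDACT2"],
      "off": [0.6, 0.71, 0.29, 0.4],
      "on": [0.4, 0.29, 0.71, 0.6]
    },
    "DACT3": {
      "parents": ["H3K27me3", "H3K4me3", "Sample"],
      "off": [0.88, 0.88, 0.12, 0.88, 0.88, 0.88, 0.12, 0.88],
      "on": [0.12, 0.12, 0.88, 0.12, 0.12, 0.12, 0.88, 0.12]
    },
    "SFRP1": {
      "parents": ["Sample", "MeSFRP1", "TRCMPLX"],
      "off": [0.88, 0.98, 0.02, 0.12, 0.2, 0.96, 0.04, 0.8],
      "on": [0.12, 0.02, 0.98, 0.88, 0.8, 0.04, 0.96, 0.2]
    },
    "SFRP2": {
      "parents": ["Sample", "MeSFRP2"],
      "off": [0.31, 0.88, 0.11, 0.69],
      "on": [0.69, 0.11, 0.89, 0.31]
    },
    "SFRP3": {
      "parents": ["Sample"],
      "off": [0.2, 0.8],
      "on": [0.8, 0.2]
    },
    "SFRP4": {
      "parents": ["Sample", "MeSFRP4"],
      "off": [0.71, 0.6, 0.4, 0.29],
      "on": [0.29, 0.4, 0.6, 0.71]
    },
    "SFRP5": {
      "parents": ["Sample", "MeSFRP5"],
      "off": [0.31, 0.89, 0.11, 0.69],
      "on": [0.69, 0.11, 0.89, 0.31]
    },
    "WIF1": {
      "parents": ["Sample", "MeWIF1", "TRCMPLX"],
      "off": [0.96, 0.91, 0.09, 0.04, 0.85, 0.47, 0.56, 0.15],
      "on": [0.04, 0.09, 0.91, 0.96, 0.15, 0.53, 0.47, 0.85]
    }
  }
}
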