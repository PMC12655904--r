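{
  "format": 1,
  "note": "Reference QSPR equations mapping the canonical 11 descriptors to pIC50 for the top-binder (TB) and commonly-exposed (CE) PFAS datasets against ERalpha/ERbeta. 'coefficients' are on the raw descriptor scale (4-decimal precision); 'normalized' are the per-SD coefficients (raw * sd of the descriptor in the originating dataset).",
  "models": {
    "TB-ERalpha": {
      "intercept": 8.03,
      "coefficients": {
        "AverageMass": 0.2222,
        "HBondDonors": -0.0312,
        "Density": 0.0887,
        "LUMO": 0.0285,
        "FreelyRotatingBonds": -0.3843,
        "HBondAcceptors": 0.0154,
        "FukuiMax": 0.0166,
        "PolarSurfaceArea": -0.0185,
        "HOMO": -0.0198,
        "LogD": 0.0485,
        "SurfaceTension": -0.0821
      },
      "normalized": {
        "AverageMass": 49.2514,
        "HBondDonors": -0.0322,
        "Density": 0.0219,
        "LUMO": 0.0434,
        "FreelyRotatingBonds": -2.3991,
        "HBondAcceptors": 0.0408,
        "FukuiMax": 0.0011,
        "PolarSurfaceArea": -0.9347,
        "HOMO": -0.0449,
        "LogD": 0.2422,
        "SurfaceTension": -1.3549
      }
    },
    "TB-ERbeta": {
      "intercept": 8.02,
      "coefficients": {
        "AverageMass": 0.1336,
        "HBondDonors": 0.0395,
        "Density": 0.1731,
        "LUMO": 0.1132,
        "FreelyRotatingBonds": -0.481,
        "HBondAcceptors": 0.0857,
        "FukuiMax": -0.0471,
        "PolarSurfaceArea": 0.0069,
        "HOMO": -0.0218,
        "LogD": 0.2245,
        "SurfaceTension": -0.0635
      },
      "normalized": {
        "AverageMass": 30.1649,
        "HBondDonors": 0.0363,
        "Density": 0.042,
        "LUMO": 0.1306,
        "FreelyRotatingBonds": -3.3561,
        "HBondAcceptors": 0.1842,
        "FukuiMax": -0.0048,
        "PolarSurfaceArea": 0.2707,
        "HOMO": -0.0459,
        "LogD": 0.8252,
        "SurfaceTension": -1.3352
      }
    },
    "CE-ERalpha": {
      "intercept": 5.95,
      "coefficients": {
        "AverageMass": -0.0198,
        "HBondDonors": -0.0874,
        "Density": 0.39,
        "LUMO": 0.0316,
        "FreelyRotatingBonds": 0.2519,
        "HBondAcceptors": -0.2744,
        "FukuiMax": -0.0485,
        "PolarSurfaceArea": 0.4216,
        "HOMO": 0.1857,
        "LogD": 0.0483,
        "SurfaceTension": -0.4753
      },
      "normalized": {
        "AverageMass": -4.1092,
        "HBondDonors": -0.0487,
        "Density": 0.0513,
        "LUMO": 0.1539,
        "FreelyRotatingBonds": 1.037,
        "HBondAcceptors": -0.4964,
        "FukuiMax": -0.0043,
        "PolarSurfaceArea": 10.6211,
        "HOMO": 0.7999,
        "LogD": 0.1923,
        "SurfaceTension": -2.3411
      }
    },
    "CE-ERbeta": {
      "intercept": 6.02,
      "coefficients": {
        "AverageMass": 0.0344,
        "HBondDonors": -0.0343,
        "Density": 0.3057,
        "LUMO": 0.0734,
        "FreelyRotatingBonds": 0.5858,
        "HBondAcceptors": -0.178,
        "FukuiMax": 0.0343,
        "PolarSurfaceArea": 0.1504,
        "HOMO": 0.0242,
        "LogD": -0.0835,
        "SurfaceTension": -0.2855
      },
      "normalized": {
        "AverageMass": 7.8995,
        "HBondDonors": -0.0212,
        "Density": 0.0445,
        "LUMO": 0.3954,
        "FreelyRotatingBonds": 2.6684,
        "HBondAcceptors": -0.3563,
        "FukuiMax": 0.0034,
        "PolarSurfaceArea": 4.1924,
        "HOMO": 0.1153,
        "LogD": -0.3679,
        "SurfaceTension": -1.556
      }
    }
  }
}
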