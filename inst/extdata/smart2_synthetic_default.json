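{
  "format": "smart2risk/coefficient-set",
  "schema_version": "1.0",
  "id": "smart2-synthetic-default",
  "version": "1.0",
  "baseline_convention": "survival",
  "coefficients": {
    "age": 0.040440150000000001,
    "sex": 0.28517894223366247,
    "current_smoking": 0.34358970439007686,
    "systolic_bp": 0.0019802626999999998,
    "non_hdl": 0.53809943000000005,
    "diabetes": 0.3148107398400336,
    "cad": 0.29266961396282004,
    "cevd": 0.35065687161316933,
    "pad": 0.22314355131420976,
    "aaa": 0.3293037471426003,
    "years_since_first_ascvd": 0.015420708999999999,
    "egfr": -3.7254169000000002e-05,
    "hscrp": 0.15117899000000001
  },
  "transforms": {
    "age": "identity",
    "sex": "identity",
    "current_smoking": "identity",
    "systolic_bp": "identity",
    "non_hdl": "log",
    "diabetes": "identity",
    "cad": "identity",
    "cevd": "identity",
    "pad": "identity",
    "aaa": "identity",
    "years_since_first_ascvd": "square",
    "egfr": "square",
    "hscrp": "log"
  },
  "centering_means": {
    "age": 60.850788999999999,
    "sex": 0.73999999999999999,
    "current_smoking": 0.29999999999999999,
    "systolic_bp": 139.12142,
    "non_hdl": 1.1933807000000001,
    "diabetes": 0.17999999999999999,
    "cad": 0.62,
    "cevd": 0.28999999999999998,
    "pad": 0.17000000000000001,
    "aaa": 0.080000000000000002,
    "years_since_first_ascvd": 13.360105000000001,
    "egfr": 6252.3851999999997,
    "hscrp": 0.69738020999999994
  },
  "baseline_survival": {
    "1": 0.97270630296725569,
    "2": 0.94751104508300499,
    "3": 0.92425289067862648,
    "4": 0.90278290816116025,
    "5": 0.88296361634265197,
    "6": 0.86466810409118,
    "7": 0.84777921766632924,
    "8": 0.83218881053528226,
    "9": 0.81779705086578991,
    "10": 0.80451178226161368
  },
  "offset_hr": 0.81000000000000005,
  "offset_term": "antithrombotic_use",
  "region_factors": {
    "europe_low": [
      1
    ]
  },
  "imputation_means": {
    "age": 61,
    "systolic_bp": 139,
    "non_hdl": 3.2999999999999998,
    "years_since_first_ascvd": 1.8,
    "egfr": 77,
    "hscrp": 2
  }
}
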