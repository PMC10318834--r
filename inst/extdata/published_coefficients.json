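{
  "provenance": "Published SAQ-to-EQ-5D-5L mapping coefficient tables (direct and indirect approaches, N = 380), rounded to 4 decimal places as printed. Covariates are SAQ subscale scores divided by 100, order pl, as, af, ts, dp.",
  "covariate_order": ["pl", "as", "af", "ts", "dp"],
  "direct": {
    "ols":   {"constant": 0.3046, "pl": 0.5271, "as": 0.0381, "af": 0.0538, "ts": 0.1018, "dp": 0.1491},
    "tobit": {"constant": 0.1855, "pl": 0.6040, "as": 0.0934, "af": 0.0838, "ts": 0.1211, "dp": 0.2431},
    "glm":   {"constant": -0.7661, "pl": 0.5712, "as": 0.0431, "af": 0.0634, "ts": 0.0939, "dp": 0.1890},
    "clad":  {"constant": 0.4421, "pl": 0.2603, "as": 0.0276, "af": 0.0983, "ts": 0.1737, "dp": 0.1343},
    "rmm":   {"constant": 0.5844, "pl": 0.1500, "as": 0.0303, "af": 0.0674, "ts": 0.0214, "dp": 0.2725}
  },
  "mixture": {
    "bm": {
      "c1_mu": {"constant": -1.5982, "pl": 3.7922, "as": 0.4226, "af": 0.6138, "ts": 0.6172, "dp": 1.3959},
      "pm_ub": {"constant": -13.9807, "pl": 5.3271, "as": 1.4955, "af": 1.9211, "ts": 1.9462, "dp": 10.2317}
    },
    "aldvmm": {
      "com1": {"constant": 0.6063, "pl": 0.0834, "as": 0.0529, "af": 0.0557, "ts": 0.0087, "dp": 0.3462},
      "com2": {"constant": -0.0005, "pl": 0.8770, "as": 0.0821, "af": 0.0973, "ts": 0.2256, "dp": 0.0341}
    }
  },
  "indirect": {
    "mo": {"beta": {"pl": -12.6193, "as": -1.2609, "af": -1.4301, "ts": -4.4563, "dp": 3.1240},
           "cuts": [-10.2116, -6.5813, -3.3392]},
    "sc": {"beta": {"pl": -11.5837, "as": -0.4644, "af": -2.6338, "ts": -2.3537, "dp": 5.0511},
           "cuts": [-4.5555, -1.9126, -1.2472]},
    "ua": {"beta": {"pl": -10.2628, "as": -1.0368, "af": -1.4646, "ts": -3.8393, "dp": 0.2211},
           "cuts": [-10.3147, -6.5026, -3.4244]},
    "pd": {"beta": {"pl": -4.4646, "as": -1.3777, "af": -1.6318, "ts": -3.6361, "dp": -5.2587},
           "cuts": [-10.3706, -6.4055, -2.6310]},
    "ad": {"beta": {"pl": -0.8718, "as": -0.7419, "af": -1.5527, "ts": 2.6952, "dp": -10.6382},
           "cuts": [-5.3762, -3.4332, 1.7840]}
  }
}
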