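{
  "effects": {
    "rr_hypertension": {
      "base": 0.98,
      "low": 0.95,
      "high": 1
    },
    "mortality": {
      "male": {
        "b20_44": {
          "base": -0.1,
          "low": -0.28,
          "high": 0.08
        },
        "b45_59": {
          "base": -0.14,
          "low": -0.57,
          "high": 0.29
        },
        "b60p": {
          "base": 0.36,
          "low": -3.01,
          "high": 3.73
        }
      },
      "female": {
        "b20_44": {
          "base": -0.05,
          "low": -0.12,
          "high": 0.03
        },
        "b45_59": {
          "base": -0.05,
          "low": -0.32,
          "high": 0.23
        },
        "b60p": {
          "base": 1.05,
          "low": -1.72,
          "high": 3.82
        }
      }
    }
  },
  "utilities": {
    "u_normotensive": {
      "base": 0.98,
      "low": 0.98,
      "high": 0.98
    },
    "u_hypertensive": {
      "base": 0.92,
      "low": 0.9,
      "high": 0.94
    }
  },
  "costs": {
    "he1": {
      "base": 359,
      "low": 243,
      "high": 977
    },
    "growth_rate": {
      "base": 0.61,
      "low": 0.5,
      "high": 0.7
    },
    "htn_annual_cost": {
      "base": 392,
      "low": 344,
      "high": 441
    },
    "ppp_rate": 3.55
  },
  "labor": {
    "baseline_offfarm_p": 0.17,
    "d_offfarm_p": {
      "b30_49": {
        "base": 0.13,
        "low": 0.07,
        "high": 0.2
      },
      "b50p": {
        "base": 0.07,
        "low": 0.03,
        "high": 0.11
      }
    },
    "d_farm_hours": {
      "b30_49": {
        "base": 1.1,
        "low": 0.84,
        "high": 1.44
      },
      "b50p": {
        "base": 1.28,
        "low": 1.07,
        "high": 1.53
      }
    },
    "annual_wage": {
      "base": 1029,
      "low": 350,
      "high": 4198
    },
    "agri_hourly": {
      "base": 1.44,
      "low": 0.47,
      "high": 2.59
    }
  },
  "econ": {
    "discount_rate": {
      "base": 0.03,
      "low": 0,
      "high": 0.05
    },
    "gdp_per_capita": 12353,
    "wtp_multiplier": 3,
    "start_age": 20,
    "end_age": 100,
    "sex_weight_male": 0.5
  },
  "schedules": {
    "mortality_csv": "mortality_cn2013_synthetic.csv",
    "incidence_csv": "htn_incidence_synthetic.csv"
  }
}
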