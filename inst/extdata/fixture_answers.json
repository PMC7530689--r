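{
  "_comment": "Hand-enumerated answer sheet for the 6-participant worked fixture (window 2017-07-01..2018-06-30, threshold 100 days). Gaps: P1 82/81/95 d (endpoint gap 97); P2 136/137 d; P5 87/87 d, last test positive. CI bounds computed with an independent chi-square quantile oracle.",
  "cascade": {
    "registered": 6,
    "excluded_no_test": 1,
    "excluded_baseline_positive": 1,
    "excluded_indeterminate_single_test": 1,
    "included": 3,
    "adherent": 2,
    "nonadherent": 1
  },
  "eligibility": {
    "P1": "included", "P2": "included", "P3": "excluded_baseline_positive",
    "P4": "excluded_indeterminate_single_test", "P5": "included",
    "P6": "excluded_no_test"
  },
  "labels": {"P1": "adherent", "P2": "nonadherent", "P5": "adherent"},
  "waived": {"P1": false, "P2": false, "P5": true},
  "n_adhering": {"P1": 3, "P2": 0, "P5": 2},
  "summary": {
    "n_tests_total": 10,
    "n_eligible_intervals": 7,
    "n_adhering_tests": 5,
    "proportion_adherent": 0.6666666666666666,
    "proportion_adhering_tests": 0.7142857142857143
  },
  "followups": {
    "P1": {"days": 258, "event": false},
    "P2": {"days": 273, "event": false},
    "P5": {"days": 130, "event": true, "exit": "2017-11-22"}
  },
  "rates_paper_dialect": {
    "adherent":    {"k": 1, "T": 1.0622861054, "rate": 94.1365979381,
                    "ci_low": 22.8007574712, "ci_high": 347.2585620142},
    "nonadherent": {"k": 0, "T": 0.7474332649, "rate": 0.0,
                    "ci_low": 0.0, "ci_high": 0.0},
    "total":       {"k": 1, "T": 1.8097193703, "rate": 55.2571860817,
                    "ci_low": 13.3838031752, "ci_high": 203.8370984289}
  },
  "table4": {
    "counts": {"Never": [1, 0], "Ever": [0, 0], "Consistent": [0, 1],
               "Uncertain": [1, 0]},
    "chi_square": 3.0, "df": 2
  },
  "table5_k2": {
    "counts": {"Better": [1, 0], "Worse": [0, 1], "Other": [1, 0]},
    "chi_square": 3.0, "df": 2
  },
  "table5_k3": {
    "counts": {"Better": [1, 0], "Worse": [0, 1], "Other": [1, 0]},
    "chi_square": 3.0, "df": 2
  },
  "table5_k4": {
    "counts": {"Better": [1, 0], "Worse": [0, 0], "Other": [0, 0]},
    "chi_square": null
  }
}
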