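{
  "beg_menu": {
    "labels": ["A", "B", "C", "D", "E", "F"],
    "payoffs": [[28, 28], [24, 36], [20, 44], [16, 52], [12, 60], [2, 70]]
  },
  "la_menu": {
    "labels": ["A", "B", "C", "D", "E", "F"],
    "payoffs": [[10, 10], [6, 18], [2, 22], [-2, 28], [-4, 35], [-5, 38]]
  },
  "mpl_panels": [
    {
      "name": "one_month",
      "sooner_amount": 25,
      "future_amounts": [26, 28, 30, 32, 35, 38],
      "delay_weeks": 2.43
    },
    {
      "name": "two_month",
      "sooner_amount": 25,
      "future_amounts": [26, 30, 35, 37, 40, 45],
      "delay_weeks": 6.71
    }
  ],
  "la_thresholds": [-0.2, 0.5, 1.1, 1.8, 2.6],
  "horizon_levels": [
    "does not plan/plans day to day",
    "the next few weeks",
    "the next few months",
    "the next year",
    "the next few years",
    "the next 5-10 years",
    "longer than 10 years"
  ]
}
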