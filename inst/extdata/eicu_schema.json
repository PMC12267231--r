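[
  {
    "name": "lactate",
    "role": "exposure",
    "kind": "continuous",
    "units": "mmol/L",
    "summary_style": "median_iqr"
  },
  {
    "name": "mortality_28d",
    "role": "outcome",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "age",
    "role": "covariate",
    "kind": "continuous",
    "units": "years",
    "summary_style": "mean_sd"
  },
  {
    "name": "gender",
    "role": "covariate",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "copd",
    "role": "covariate",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "chf",
    "role": "covariate",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "ami",
    "role": "covariate",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "dm",
    "role": "covariate",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "hr",
    "role": "covariate",
    "kind": "continuous",
    "units": "beats/min",
    "summary_style": "mean_sd"
  },
  {
    "name": "temperature",
    "role": "covariate",
    "kind": "continuous",
    "units": "degC",
    "summary_style": "mean_sd"
  },
  {
    "name": "hemoglobin",
    "role": "covariate",
    "kind": "continuous",
    "units": "g/dL",
    "summary_style": "mean_sd"
  },
  {
    "name": "potassium",
    "role": "covariate",
    "kind": "continuous",
    "units": "mmol/L",
    "summary_style": "mean_sd"
  },
  {
    "name": "rbc",
    "role": "covariate",
    "kind": "continuous",
    "units": "M/mcL",
    "summary_style": "mean_sd"
  },
  {
    "name": "sodium",
    "role": "covariate",
    "kind": "continuous",
    "units": "mmol/L",
    "summary_style": "mean_sd"
  },
  {
    "name": "wbc",
    "role": "covariate",
    "kind": "continuous",
    "units": "1e9/L",
    "summary_style": "median_iqr"
  },
  {
    "name": "bicarbonate",
    "role": "covariate",
    "kind": "continuous",
    "units": "mmol/L",
    "summary_style": "mean_sd"
  },
  {
    "name": "rdw",
    "role": "covariate",
    "kind": "continuous",
    "units": "%",
    "summary_style": "mean_sd"
  },
  {
    "name": "bun",
    "role": "covariate",
    "kind": "continuous",
    "units": "mg/dL",
    "summary_style": "median_iqr"
  },
  {
    "name": "apache_iv",
    "role": "covariate",
    "kind": "continuous",
    "units": "points",
    "summary_style": "mean_sd"
  },
  {
    "name": "sofa",
    "role": "covariate",
    "kind": "continuous",
    "units": "points",
    "summary_style": "median_iqr"
  },
  {
    "name": "unit_type",
    "role": "covariate",
    "kind": "categorical",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "icu_los_days",
    "role": "admin",
    "kind": "continuous",
    "units": "days",
    "summary_style": "median_iqr"
  },
  {
    "name": "icu_los_hours",
    "role": "admin",
    "kind": "continuous",
    "units": "hours",
    "summary_style": "mean_sd"
  },
  {
    "name": "sepsis_flag",
    "role": "admin",
    "kind": "binary",
    "units": "",
    "summary_style": "count_pct"
  },
  {
    "name": "lactate_n_measurements",
    "role": "admin",
    "kind": "continuous",
    "units": "count",
    "summary_style": "mean_sd"
  },
  {
    "name": "death_hours",
    "role": "admin",
    "kind": "continuous",
    "units": "hours",
    "summary_style": "mean_sd"
  }
]
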