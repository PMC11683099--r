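[
  {
    "id": "h_total_health_exp",
    "name": "Total health expenditure",
    "system": "health",
    "layer": "Aggregate allocation: financial",
    "direction": 1
  },
  {
    "id": "h_total_institutions",
    "name": "Total number of medical institutions",
    "system": "health",
    "layer": "Aggregate allocation: material",
    "direction": 1
  },
  {
    "id": "h_total_beds",
    "name": "Total number of beds in medical institutions",
    "system": "health",
    "layer": "Aggregate allocation: material",
    "direction": 1
  },
  {
    "id": "h_total_physicians",
    "name": "Total number of practicing (assistant) physicians",
    "system": "health",
    "layer": "Aggregate allocation: human",
    "direction": 1
  },
  {
    "id": "h_total_nurses",
    "name": "Total number of registered nurses",
    "system": "health",
    "layer": "Aggregate allocation: human",
    "direction": 1
  },
  {
    "id": "h_pc_health_exp",
    "name": "Per capita health expenditure",
    "system": "health",
    "layer": "Per capita allocation: financial",
    "direction": 1
  },
  {
    "id": "h_institutions_per_1000",
    "name": "Medical institutions per 1,000 population",
    "system": "health",
    "layer": "Per capita allocation: material",
    "direction": 1
  },
  {
    "id": "h_beds_per_1000",
    "name": "Beds in medical institutions per 1,000 population",
    "system": "health",
    "layer": "Per capita allocation: material",
    "direction": 1
  },
  {
    "id": "h_physicians_per_1000",
    "name": "Practicing (assistant) physicians per 1,000 population",
    "system": "health",
    "layer": "Per capita allocation: human",
    "direction": 1
  },
  {
    "id": "h_nurses_per_1000",
    "name": "Registered nurses per 1,000 population",
    "system": "health",
    "layer": "Per capita allocation: human",
    "direction": 1
  },
  {
    "id": "h_institution_density",
    "name": "Distribution density of medical institutions",
    "system": "health",
    "layer": "Per land allocation: material",
    "direction": 1
  },
  {
    "id": "h_bed_density",
    "name": "Distribution density of beds in medical institutions",
    "system": "health",
    "layer": "Per land allocation: material",
    "direction": 1
  },
  {
    "id": "h_physician_density",
    "name": "Distribution density of practicing (assistant) physicians",
    "system": "health",
    "layer": "Per land allocation: human",
    "direction": 1
  },
  {
    "id": "h_nurse_density",
    "name": "Distribution density of registered nurses",
    "system": "health",
    "layer": "Per land allocation: human",
    "direction": 1
  },
  {
    "id": "e_gdp",
    "name": "GDP",
    "system": "economy",
    "layer": "Economic scale: productivity",
    "direction": 1
  },
  {
    "id": "e_retail_sales",
    "name": "Total retail sales of social consumer goods",
    "system": "economy",
    "layer": "Economic scale: consumption",
    "direction": 1
  },
  {
    "id": "e_trade_volume",
    "name": "Total volume of imports and exports",
    "system": "economy",
    "layer": "Economic scale: trade",
    "direction": 1
  },
  {
    "id": "e_secondary_share",
    "name": "Proportion of secondary industry to GDP",
    "system": "economy",
    "layer": "Economic structure: industrial",
    "direction": 1
  },
  {
    "id": "e_tertiary_share",
    "name": "Proportion of tertiary industry to GDP",
    "system": "economy",
    "layer": "Economic structure: industrial",
    "direction": 1
  },
  {
    "id": "e_tech_market_share",
    "name": "Proportion of technology market turnover to GDP",
    "system": "economy",
    "layer": "Economic structure: technical",
    "direction": 1
  },
  {
    "id": "e_fai_growth",
    "name": "Growth rate of fixed-asset investment",
    "system": "economy",
    "layer": "Economic dynamics: investment",
    "direction": 1
  },
  {
    "id": "e_budget_exp_growth",
    "name": "Growth rate of general public budget expenditure",
    "system": "economy",
    "layer": "Economic dynamics: investment",
    "direction": 1
  },
  {
    "id": "e_pc_retail_sales",
    "name": "Total retail sales of consumer goods per capita",
    "system": "economy",
    "layer": "Economic dynamics: consumption",
    "direction": 1
  },
  {
    "id": "e_trade_growth",
    "name": "Growth rate of exports and imports",
    "system": "economy",
    "layer": "Economic dynamics: trade",
    "direction": 1
  },
  {
    "id": "e_patents_granted",
    "name": "Number of patents granted",
    "system": "economy",
    "layer": "Economic dynamics: innovation",
    "direction": 1
  },
  {
    "id": "e_pc_disposable_income",
    "name": "Per capita disposable income",
    "system": "economy",
    "layer": "Economic benefits: income",
    "direction": 1
  },
  {
    "id": "e_cpi",
    "name": "CPI",
    "system": "economy",
    "layer": "Economic benefits: price fluctuation",
    "direction": -1
  },
  {
    "id": "e_unemployed",
    "name": "Urban registered unemployed population",
    "system": "economy",
    "layer": "Economic benefits: employment",
    "direction": -1
  }
]
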