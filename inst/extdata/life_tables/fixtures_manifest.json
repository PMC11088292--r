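{
  "kind": "synthetic_life_tables",
  "n_tables": 6,
  "tables": {
    "ESP_male": {
      "file": "life_table_ESP_male.csv",
      "country": "ESP",
      "sex": "male",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 2.77836112e-05,
        "gompertz_beta": 0.092
      },
      "remaining_le_60": 23.6000135038389
    },
    "ESP_female": {
      "file": "life_table_ESP_female.csv",
      "country": "ESP",
      "sex": "female",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 6.02432193e-06,
        "gompertz_beta": 0.105
      },
      "remaining_le_60": 27.5999983953474
    },
    "FRA_male": {
      "file": "life_table_FRA_male.csv",
      "country": "FRA",
      "sex": "male",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 2.84511281e-05,
        "gompertz_beta": 0.092
      },
      "remaining_le_60": 23.4000055334729
    },
    "FRA_female": {
      "file": "life_table_FRA_female.csv",
      "country": "FRA",
      "sex": "female",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 6.10569566e-06,
        "gompertz_beta": 0.105
      },
      "remaining_le_60": 27.4999989401508
    },
    "GER_male": {
      "file": "life_table_GER_male.csv",
      "country": "GER",
      "sex": "male",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 3.35862971e-05,
        "gompertz_beta": 0.092
      },
      "remaining_le_60": 21.9998965831814
    },
    "GER_female": {
      "file": "life_table_GER_female.csv",
      "country": "GER",
      "sex": "female",
      "gompertz_makeham": {
        "makeham_lambda": 0.0005,
        "gompertz_alpha": 7.8298062e-06,
        "gompertz_beta": 0.105
      },
      "remaining_le_60": 25.6000108503513
    }
  }
}
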