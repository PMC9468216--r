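[
  {
    "variable": "physical_activity",
    "code": 1,
    "label": "Light",
    "ordinal": true
  },
  {
    "variable": "physical_activity",
    "code": 2,
    "label": "Moderate",
    "ordinal": true
  },
  {
    "variable": "physical_activity",
    "code": 3,
    "label": "Vigorous",
    "ordinal": true
  },
  {
    "variable": "sex",
    "code": 1,
    "label": "Men",
    "ordinal": false
  },
  {
    "variable": "sex",
    "code": 2,
    "label": "Women",
    "ordinal": false
  },
  {
    "variable": "age",
    "code": 1,
    "label": "<55",
    "ordinal": true
  },
  {
    "variable": "age",
    "code": 2,
    "label": "55-65",
    "ordinal": true
  },
  {
    "variable": "age",
    "code": 3,
    "label": "65-75",
    "ordinal": true
  },
  {
    "variable": "age",
    "code": 4,
    "label": ">=75",
    "ordinal": true
  },
  {
    "variable": "education",
    "code": 1,
    "label": "<=Primary school",
    "ordinal": true
  },
  {
    "variable": "education",
    "code": 2,
    "label": "<=Middle school",
    "ordinal": true
  },
  {
    "variable": "education",
    "code": 3,
    "label": "<College",
    "ordinal": true
  },
  {
    "variable": "education",
    "code": 4,
    "label": ">=College",
    "ordinal": true
  },
  {
    "variable": "residence",
    "code": 1,
    "label": "Town",
    "ordinal": false
  },
  {
    "variable": "residence",
    "code": 2,
    "label": "Combination",
    "ordinal": false
  },
  {
    "variable": "residence",
    "code": 3,
    "label": "Village",
    "ordinal": false
  },
  {
    "variable": "residence",
    "code": 4,
    "label": "Special area",
    "ordinal": false
  },
  {
    "variable": "marital_status",
    "code": 1,
    "label": "Married",
    "ordinal": false
  },
  {
    "variable": "marital_status",
    "code": 2,
    "label": "Divorced",
    "ordinal": false
  },
  {
    "variable": "marital_status",
    "code": 3,
    "label": "Widowed",
    "ordinal": false
  },
  {
    "variable": "marital_status",
    "code": 4,
    "label": "Never married",
    "ordinal": false
  },
  {
    "variable": "sleep_duration",
    "code": 1,
    "label": "<=5h",
    "ordinal": true
  },
  {
    "variable": "sleep_duration",
    "code": 2,
    "label": "5-6h",
    "ordinal": true
  },
  {
    "variable": "sleep_duration",
    "code": 3,
    "label": "6-7h",
    "ordinal": true
  },
  {
    "variable": "sleep_duration",
    "code": 4,
    "label": "7-8h",
    "ordinal": true
  },
  {
    "variable": "sleep_duration",
    "code": 5,
    "label": ">8h",
    "ordinal": true
  },
  {
    "variable": "nap",
    "code": 1,
    "label": "0min",
    "ordinal": true
  },
  {
    "variable": "nap",
    "code": 2,
    "label": "<=30min",
    "ordinal": true
  },
  {
    "variable": "nap",
    "code": 3,
    "label": ">30min",
    "ordinal": true
  },
  {
    "variable": "smoking",
    "code": 0,
    "label": "No",
    "ordinal": false
  },
  {
    "variable": "smoking",
    "code": 1,
    "label": "Yes",
    "ordinal": false
  },
  {
    "variable": "alcohol",
    "code": 0,
    "label": "No",
    "ordinal": false
  },
  {
    "variable": "alcohol",
    "code": 1,
    "label": "Yes",
    "ordinal": false
  },
  {
    "variable": "mmd",
    "code": 0,
    "label": "No",
    "ordinal": false
  },
  {
    "variable": "mmd",
    "code": 1,
    "label": "Yes",
    "ordinal": false
  }
]
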