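[
  {"label": 1,  "name": "lateral ventricle L", "hemisphere": "left",    "paired_label": 2},
  {"label": 2,  "name": "lateral ventricle R", "hemisphere": "right",   "paired_label": 1},
  {"label": 3,  "name": "caudate L",           "hemisphere": "left",    "paired_label": 4},
  {"label": 4,  "name": "caudate R",           "hemisphere": "right",   "paired_label": 3},
  {"label": 5,  "name": "putamen L",           "hemisphere": "left",    "paired_label": 6},
  {"label": 6,  "name": "putamen R",           "hemisphere": "right",   "paired_label": 5},
  {"label": 7,  "name": "thalamus L",          "hemisphere": "left",    "paired_label": 8},
  {"label": 8,  "name": "thalamus R",          "hemisphere": "right",   "paired_label": 7},
  {"label": 9,  "name": "pallidum L",          "hemisphere": "left",    "paired_label": 10},
  {"label": 10, "name": "pallidum R",          "hemisphere": "right",   "paired_label": 9},
  {"label": 11, "name": "hippocampus L",       "hemisphere": "left",    "paired_label": 12},
  {"label": 12, "name": "hippocampus R",       "hemisphere": "right",   "paired_label": 11},
  {"label": 13, "name": "amygdala L",          "hemisphere": "left",    "paired_label": 14},
  {"label": 14, "name": "amygdala R",          "hemisphere": "right",   "paired_label": 13},
  {"label": 15, "name": "accumbens L",         "hemisphere": "left",    "paired_label": 16},
  {"label": 16, "name": "accumbens R",         "hemisphere": "right",   "paired_label": 15},
  {"label": 17, "name": "brainstem",           "hemisphere": "midline", "paired_label": null}
]
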