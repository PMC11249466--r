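{
  "placeholder": true,
  "adhesiveness": {
    "dis_class_a": 1,
    "dis_class_b": 1,
    "standard": 1
  },
  "position": {
    "onlay": 1,
    "retromuscular": 1,
    "preperitoneal": 1,
    "intraperitoneal_underlay": 1
  },
  "fixation": {
    "none": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ],
    "absorbable_tack": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ],
    "nonresorbable_suture": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ],
    "pull_out_suture": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ],
    "bone_anchor": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ],
    "fibrin_glue": [
      {
        "max_points": null,
        "multiplier": 1
      }
    ]
  },
  "peritoneal_closure_factor": 0,
  "fascial_closure_factor": 0
}
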