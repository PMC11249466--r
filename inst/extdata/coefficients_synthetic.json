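{
  "placeholder": false,
  "adhesiveness": {
    "dis_class_a": 4,
    "dis_class_b": 2,
    "standard": 1
  },
  "position": {
    "onlay": 1,
    "retromuscular": 2,
    "preperitoneal": 1.5,
    "intraperitoneal_underlay": 1.2
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
        "max_points": 25,
        "multiplier": 1.5
      },
      {
        "max_points": 60,
        "multiplier": 2
      },
      {
        "max_points": 120,
        "multiplier": 2.5
      },
      {
        "max_points": null,
        "multiplier": 3
      }
    ],
    "nonresorbable_suture": [
      {
        "max_points": 20,
        "multiplier": 2
      },
      {
        "max_points": 60,
        "multiplier": 3.5
      },
      {
        "max_points": 120,
        "multiplier": 5
      },
      {
        "max_points": null,
        "multiplier": 6
      }
    ],
    "pull_out_suture": [
      {
        "max_points": null,
        "multiplier": 4
      }
    ],
    "bone_anchor": [
      {
        "max_points": 100,
        "multiplier": 5
      },
      {
        "max_points": null,
        "multiplier": 8
      }
    ],
    "fibrin_glue": [
      {
        "max_points": null,
        "multiplier": 1.5
      }
    ]
  },
  "peritoneal_closure_factor": 10,
  "fascial_closure_factor": 20
}
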