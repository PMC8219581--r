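{
  "schema_version": "1",
  "name": "orientation-discrimination-tutorial",
  "settings": {
    "display": {
      "model_name": "generic-tablet",
      "width_px": 800,
      "height_px": 600,
      "pixels_per_cm": 52,
      "refresh_rate": 60,
      "max_luminance": 600,
      "viewing_distance": 57.3
    },
    "audio_rate": 44100,
    "av_offset_ms": 0,
    "rng_seed": 1
  },
  "stimuli": [
    {
      "name": "stimulus1",
      "type": "patch",
      "shape": "cross",
      "properties": {
        "size_x": {"mode": "constant", "value": 1, "unit": "deg"},
        "size_y": {"mode": "constant", "value": 1, "unit": "deg"},
        "color": {"mode": "constant", "value": [1, 1, 1]}
      }
    },
    {
      "name": "stimulus2",
      "type": "grating",
      "shape": "ellipse",
      "properties": {
        "size_x": {"mode": "constant", "value": 6, "unit": "deg"},
        "size_y": {"mode": "constant", "value": 6, "unit": "deg"},
        "spatial_frequency": {"mode": "constant", "value": 2, "unit": "cpd"},
        "mean_luminance": {"mode": "constant", "value": 0.5},
        "contrast": {"mode": "constant", "value": 0.8},
        "envelope_sigma": {"mode": "constant", "value": 1, "unit": "deg"},
        "gratingRotation": {"mode": "variable",
                            "variable": "scene2_object1_gratingRotation",
                            "unit": "rad"}
      }
    }
  ],
  "sections": [
    {
      "name": "section1",
      "repetitions": 20,
      "scenes": [
        {
          "name": "scene1",
          "duration": {"value": 0.5, "unit": "s"},
          "objects": ["stimulus1"],
          "response": null
        },
        {
          "name": "scene2",
          "duration": {"value": 1.0, "unit": "s"},
          "objects": ["stimulus2"],
          "response": {
            "kind": "left_or_right",
            "values": {"left": -1, "right": 1},
            "timeout": null
          }
        }
      ],
      "variables": [
        {
          "target": "scene2_object1_gratingRotation",
          "list": "list1",
          "selection_method": "all_values_random_order",
          "adaptive_config": null
        }
      ],
      "next_section": "END"
    }
  ],
  "lists": [
    {
      "name": "list1",
      "values": [-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03]
    }
  ],
  "first_section": "section1"
}
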