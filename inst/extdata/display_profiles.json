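[
  {
    "model_name": "generic-tablet",
    "width_px": 800, "height_px": 600, "pixels_per_cm": 52,
    "refresh_rate": 60, "max_luminance": 600, "viewing_distance": 57.3
  },
  {
    "model_name": "tablet-10in-60hz",
    "width_px": 2160, "height_px": 1620, "pixels_per_cm": 104,
    "refresh_rate": 60, "max_luminance": 500, "viewing_distance": 40
  },
  {
    "model_name": "tablet-pro-120hz",
    "width_px": 2224, "height_px": 1668, "pixels_per_cm": 104,
    "refresh_rate": 120, "max_luminance": 600, "viewing_distance": 40
  },
  {
    "model_name": "phone-60hz",
    "width_px": 2436, "height_px": 1125, "pixels_per_cm": 181,
    "refresh_rate": 60, "max_luminance": 625, "viewing_distance": 30
  }
]
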