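{
  "universal": {"p0": 245, "ps": 3542},
  "geometries": {
    "geometry1": {
      "geometry": {"ssd_cm": 90, "field_cm": 20, "depth_cm": 10},
      "full": {"P0": 247, "Ps": 3585, "m": 30.80},
      "methods": {
        "Ia":   {"P0": 245, "Ps": 3542, "m": 31.28},
        "Ib":   {"P0": 245, "Ps": 3542, "m": 31.17},
        "IIa":  {"P0": 247, "Ps": 3542, "m": 31.23},
        "IIb":  {"P0": 247, "Ps": 3542, "m": 31.11},
        "IIIa": {"P0": 247, "Ps": 3558, "m": 30.91},
        "IIIb": {"P0": 247, "Ps": 3538, "m": 31.10}
      }
    },
    "geometry2": {
      "geometry": {"ssd_cm": 95, "field_cm": 10, "depth_cm": 5},
      "full": {"P0": 240, "Ps": 3577, "m": 33.58},
      "methods": {
        "Ia":   {"P0": 245, "Ps": 3542, "m": 33.37},
        "Ib":   {"P0": 245, "Ps": 3542, "m": 33.48},
        "IIa":  {"P0": 240, "Ps": 3542, "m": 33.50},
        "IIb":  {"P0": 240, "Ps": 3542, "m": 33.63},
        "IIIa": {"P0": 240, "Ps": 3494, "m": 33.95},
        "IIIb": {"P0": 240, "Ps": 3506, "m": 33.80}
      }
    },
    "geometry3": {
      "geometry": {"ssd_cm": 90, "field_cm": 5, "depth_cm": 10},
      "full": {"P0": 254, "Ps": 3209, "m": 40.18},
      "methods": {
        "Ia":   {"P0": 245, "Ps": 3542, "m": 37.62},
        "Ib":   {"P0": 245, "Ps": 3542, "m": 38.28},
        "IIa":  {"P0": 254, "Ps": 3542, "m": 37.36},
        "IIb":  {"P0": 254, "Ps": 3542, "m": 37.98},
        "IIIa": {"P0": 254, "Ps": 3200, "m": 40.19},
        "IIIb": {"P0": 254, "Ps": 3200, "m": 40.16}
      }
    }
  }
}
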