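{
  "name": "modified-M5 four-layer hemilaryngeal cross-section (synthetic layout)",
  "units": "mm",
  "contact_plane_x": 8.4,
  "depth": 14,
  "z_in": -3.6,
  "z_out": 0,
  "outer": [
    [0, 0],
    [0, -10.7],
    [4.3, -10.7],
    [5.8, -5.6],
    [7.4, -3.6],
    [8.2, -2],
    [8.2, -0.9],
    [8.05, -0.4],
    [7.7, 0]
  ],
  "layers": {
    "epithelium": [
      [4.3, -10.7],
      [4.4121, -10.3187],
      [4.5243, -9.9374],
      [4.6364, -9.5561],
      [4.7486, -9.1748],
      [4.8607, -8.7935],
      [4.9729, -8.4121],
      [5.085, -8.0308],
      [5.1972, -7.6495],
      [5.3093, -7.2682],
      [5.4215, -6.8869],
      [5.5336, -6.5056],
      [5.6458, -6.1243],
      [5.7579, -5.743],
      [5.9538, -5.4077],
      [6.2, -5.1],
      [6.4462, -4.7923],
      [6.6923, -4.4846],
      [6.9385, -4.1769],
      [7.1846, -3.8692],
      [7.4222, -3.5556],
      [7.6, -3.2],
      [7.7778, -2.8444],
      [7.9556, -2.4889],
      [8.1333, -2.1333],
      [8.2, -1.75],
      [8.2, -1.35],
      [8.2, -0.95],
      [8.1045, -0.5818],
      [7.9227, -0.2545],
      [7.7, 0],
      [7.4366, -0.2305],
      [7.6593, -0.485],
      [7.7693, -0.6824],
      [7.85, -0.95],
      [7.85, -1.35],
      [7.85, -1.75],
      [7.8203, -1.9768],
      [7.6425, -2.3324],
      [7.4647, -2.6879],
      [7.287, -3.0435],
      [7.1092, -3.399],
      [6.9113, -3.6506],
      [6.6652, -3.9583],
      [6.419, -4.266],
      [6.1728, -4.5737],
      [5.9267, -4.8814],
      [5.6805, -5.189],
      [5.4222, -5.6442],
      [5.31, -6.0255],
      [5.1979, -6.4068],
      [5.0857, -6.7882],
      [4.9736, -7.1695],
      [4.8614, -7.5508],
      [4.7493, -7.9321],
      [4.6371, -8.3134],
      [4.525, -8.6947],
      [4.4128, -9.076],
      [4.3007, -9.4573],
      [4.1885, -9.8386],
      [4.0764, -10.2199],
      [3.9642, -10.6012]
    ],
    "slp": [
      [3.9642, -10.6012],
      [4.0764, -10.2199],
      [4.1885, -9.8386],
      [4.3007, -9.4573],
      [4.4128, -9.076],
      [4.525, -8.6947],
      [4.6371, -8.3134],
      [4.7493, -7.9321],
      [4.8614, -7.5508],
      [4.9736, -7.1695],
      [5.0857, -6.7882],
      [5.1979, -6.4068],
      [5.31, -6.0255],
      [5.4222, -5.6442],
      [5.6805, -5.189],
      [5.9267, -4.8814],
      [6.1728, -4.5737],
      [6.419, -4.266],
      [6.6652, -3.9583],
      [6.9113, -3.6506],
      [7.1092, -3.399],
      [7.287, -3.0435],
      [7.4647, -2.6879],
      [7.6425, -2.3324],
      [7.8203, -1.9768],
      [7.85, -1.75],
      [7.85, -1.35],
      [7.85, -0.95],
      [7.7693, -0.6824],
      [7.6593, -0.485],
      [7.4366, -0.2305],
      [5.9314, -1.5475],
      [6.1542, -1.802],
      [5.8537, -1.2571],
      [5.85, -0.95],
      [5.85, -1.35],
      [5.85, -1.75],
      [6.0314, -1.0824],
      [5.8537, -1.4379],
      [5.6759, -1.7935],
      [5.4981, -2.149],
      [5.3203, -2.5046],
      [5.3496, -2.4012],
      [5.1034, -2.7089],
      [4.8573, -3.0166],
      [4.6111, -3.3243],
      [4.365, -3.632],
      [4.1188, -3.9397],
      [3.5034, -5.0799],
      [3.3913, -5.4612],
      [3.2791, -5.8425],
      [3.167, -6.2238],
      [3.0548, -6.6051],
      [2.9427, -6.9864],
      [2.8305, -7.3678],
      [2.7184, -7.7491],
      [2.6062, -8.1304],
      [2.4941, -8.5117],
      [2.3819, -8.893],
      [2.2698, -9.2743],
      [2.1576, -9.6556],
      [2.0455, -10.0369]
    ],
    "ligament": [
      [2.0455, -10.0369],
      [2.1576, -9.6556],
      [2.2698, -9.2743],
      [2.3819, -8.893],
      [2.4941, -8.5117],
      [2.6062, -8.1304],
      [2.7184, -7.7491],
      [2.8305, -7.3678],
      [2.9427, -6.9864],
      [3.0548, -6.6051],
      [3.167, -6.2238],
      [3.2791, -5.8425],
      [3.3913, -5.4612],
      [3.5034, -5.0799],
      [4.1188, -3.9397],
      [4.365, -3.632],
      [4.6111, -3.3243],
      [4.8573, -3.0166],
      [5.1034, -2.7089],
      [5.3496, -2.4012],
      [5.3203, -2.5046],
      [5.4981, -2.149],
      [5.6759, -1.7935],
      [5.8537, -1.4379],
      [6.0314, -1.0824],
      [5.85, -1.75],
      [5.85, -1.35],
      [5.85, -0.95],
      [5.8537, -1.2571],
      [6.1542, -1.802],
      [5.9314, -1.5475],
      [5.1789, -2.206],
      [5.4016, -2.4605],
      [4.8958, -1.5444],
      [4.85, -0.95],
      [4.85, -1.35],
      [4.85, -1.75],
      [5.137, -0.6352],
      [4.9592, -0.9907],
      [4.7814, -1.3463],
      [4.6037, -1.7018],
      [4.4259, -2.0574],
      [4.5687, -1.7765],
      [4.3226, -2.0842],
      [4.0764, -2.3919],
      [3.8302, -2.6996],
      [3.5841, -3.0073],
      [3.3379, -3.315],
      [2.5441, -4.7977],
      [2.4319, -5.179],
      [2.3198, -5.5604],
      [2.2076, -5.9417],
      [2.0955, -6.323],
      [1.9833, -6.7043],
      [1.8712, -7.0856],
      [1.759, -7.4669],
      [1.6469, -7.8482],
      [1.5347, -8.2295],
      [1.4226, -8.6108],
      [1.3104, -8.9921],
      [1.1983, -9.3734],
      [1.0861, -9.7547]
    ]
  },
  "fixed_boundaries": ["left", "bottom"],
  "surface_chain": [
    [4.3, -10.7],
    [5.8, -5.6],
    [7.4, -3.6],
    [8.2, -2],
    [8.2, -0.9],
    [8.05, -0.4],
    [7.7, 0]
  ]
}
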