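{
  "duration": 1.64,
  "frame_rate": 146,
  "events": [
    {
      "label": "d",
      "delta": [-1, 1, 1],
      "mu": 1.1,
      "tp": 0.14,
      "tw": 0.1,
      "th": 0,
      "consonant": true
    },
    {
      "label": "ao",
      "delta": [1, -1, 0],
      "mu": 0.5,
      "tp": 0.34,
      "tw": 0.21,
      "th": 0,
      "consonant": false
    },
    {
      "label": "g",
      "delta": [-1, 1, -1],
      "mu": 1,
      "tp": 0.55,
      "tw": 0.14,
      "th": 0.03,
      "consonant": true
    },
    {
      "label": "eh",
      "delta": [-0.5, 0.7, 0.3],
      "mu": 0.5,
      "tp": 0.79,
      "tw": 0.21,
      "th": 0,
      "consonant": false
    },
    {
      "label": "ih",
      "delta": [-0.8, 1, 0.5],
      "mu": 0.5,
      "tp": 0.86,
      "tw": 0.21,
      "th": 0,
      "consonant": false
    },
    {
      "label": "t",
      "delta": [-1, 1, 1],
      "mu": 1,
      "tp": 0.92,
      "tw": 0.1,
      "th": 0,
      "consonant": true
    },
    {
      "label": "b",
      "delta": [-1, -1, -1],
      "mu": 1,
      "tp": 1.13,
      "tw": 0.07,
      "th": 0.03,
      "consonant": true
    },
    {
      "label": "ah",
      "delta": [1, -0.5, 0],
      "mu": 0.5,
      "tp": 1.27,
      "tw": 0.24,
      "th": 0,
      "consonant": false
    },
    {
      "label": "g",
      "delta": [-1, 1, -1],
      "mu": 1,
      "tp": 1.47,
      "tw": 0.14,
      "th": 0.01,
      "consonant": true
    }
  ],
  "f0": [
    {
      "time": 0,
      "f0": 105
    },
    {
      "time": 0.6,
      "f0": 125
    },
    {
      "time": 1.2,
      "f0": 110
    },
    {
      "time": 1.64,
      "f0": 85
    }
  ],
  "abduction": [
    {
      "start": 0.86,
      "end": 1.02
    }
  ]
}
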