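{
  "name": "iks-free",
  "constants": {
    "F": 96485.33212,
    "R": 8.314462618,
    "T": 293.15
  },
  "states": [
    {
      "label": "C1",
      "conducting": false
    },
    {
      "label": "C2",
      "conducting": false
    },
    {
      "label": "C3",
      "conducting": false
    },
    {
      "label": "O1",
      "conducting": true
    },
    {
      "label": "O2",
      "conducting": true
    },
    {
      "label": "C2s",
      "conducting": false
    }
  ],
  "transitions": [
    {
      "label": "alpha1",
      "from": "C1",
      "to": "C2",
      "amplitude": 1,
      "charge": 0.47
    },
    {
      "label": "beta1",
      "from": "C2",
      "to": "C1",
      "amplitude": 0.2,
      "charge": -0.35
    },
    {
      "label": "alpha2",
      "from": "C2",
      "to": "C3",
      "amplitude": 0.46,
      "charge": 0.47
    },
    {
      "label": "beta2",
      "from": "C3",
      "to": "C2",
      "amplitude": 3.3,
      "charge": -0.35
    },
    {
      "label": "alpha3",
      "from": "C3",
      "to": "O1",
      "amplitude": 24,
      "charge": 0.06
    },
    {
      "label": "beta3",
      "from": "O1",
      "to": "C3",
      "amplitude": 19,
      "charge": -0.007
    },
    {
      "label": "epsilon",
      "from": "O1",
      "to": "O2",
      "amplitude": 4.6,
      "charge": 0.8
    },
    {
      "label": "delta",
      "from": "O2",
      "to": "O1",
      "amplitude": 1.4,
      "charge": -0.7
    },
    {
      "label": "gamma",
      "from": "C2",
      "to": "C2s",
      "amplitude": 10,
      "charge": 0
    },
    {
      "label": "rho",
      "from": "C2s",
      "to": "C2",
      "amplitude": 10,
      "charge": 0
    }
  ]
}
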