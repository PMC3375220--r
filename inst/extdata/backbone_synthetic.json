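{
  "name": "synthetic-ca1",
  "description": "Synthetic backbone profile: generic HH channel set (Na with a distally-decreasing trunk gradient, delayed rectifier, A-type K with a distally-increasing gradient, an L-type-like HVA calcium channel with the proximal-equalization rule, and a small persistent Na current supporting the somatic after-depolarization). Calibrated once to give a propagating, distance-attenuating BAP and CA1-like spine calcium signals on the synthetic morphology. Not a reproduction of any published density set; a reproduction profile can be dropped into this schema.",
  "temperature_c": 34,
  "v_init_mV": -65,
  "ap_threshold_mV": 0,
  "ca_e_mM": 2,
  "passive": {
    "cm_uF_cm2": 1,
    "rm_kohm_cm2": {
      "default": 30,
      "soma": 40,
      "basal": 30,
      "axon": 30,
      "apical_trunk": 10,
      "oblique": 10,
      "spine": 10
    },
    "ra_ohm_cm": {
      "default": 100,
      "apical_trunk": 50,
      "oblique": 50,
      "spine": 50
    },
    "e_pas_mV": -65
  },
  "mechanisms": [
    {
      "name": "na",
      "erev_mV": 55,
      "is_calcium": false,
      "density_mS_cm2": {
        "soma": 60,
        "axon": 100,
        "apical_trunk": 28,
        "oblique": 60,
        "basal": 20,
        "default": 0
      },
      "gates": [
        {
          "power": 3,
          "inf_vhalf": -31,
          "inf_k": 6.5,
          "tau_type": "bell",
          "tau": [
            0.04,
            0.3,
            -38,
            14,
            14
          ],
          "q10_tau_scale": 1
        },
        {
          "power": 1,
          "inf_vhalf": -56,
          "inf_k": -6.5,
          "tau_type": "bell",
          "tau": [
            0.4,
            6,
            -52,
            14,
            14
          ],
          "q10_tau_scale": 1
        }
      ],
      "gradient": {
        "regions": [
          "apical_trunk"
        ],
        "per_100um": -0.2,
        "min_factor": 0.02,
        "max_factor": 1
      }
    },
    {
      "name": "kdr",
      "erev_mV": -77,
      "is_calcium": false,
      "density_mS_cm2": {
        "soma": 30,
        "axon": 40,
        "apical_trunk": 5,
        "oblique": 40,
        "basal": 8,
        "default": 0
      },
      "gates": [
        {
          "power": 2,
          "inf_vhalf": -25,
          "inf_k": 10,
          "tau_type": "bell",
          "tau": [
            0.8,
            4,
            -30,
            20,
            20
          ],
          "q10_tau_scale": 1
        }
      ]
    },
    {
      "name": "ka",
      "erev_mV": -77,
      "is_calcium": false,
      "density_mS_cm2": {
        "soma": 5,
        "axon": 0,
        "apical_trunk": 6,
        "oblique": 20,
        "basal": 4,
        "default": 0
      },
      "gradient": {
        "regions": [
          "apical_trunk",
          "oblique"
        ],
        "per_100um": 2.6,
        "min_factor": 1,
        "max_factor": 8
      },
      "gates": [
        {
          "power": 1,
          "inf_vhalf": 0,
          "inf_k": 9,
          "tau_type": "const",
          "tau": 0.3,
          "q10_tau_scale": 1
        },
        {
          "power": 1,
          "inf_vhalf": -66,
          "inf_k": -7,
          "tau_type": "bell",
          "tau": [
            4,
            20,
            -60,
            18,
            18
          ],
          "q10_tau_scale": 1
        }
      ]
    },
    {
      "name": "cal",
      "erev_mV": 0,
      "is_calcium": true,
      "density_mS_cm2": {
        "soma": 2,
        "apical_trunk": 0.15,
        "oblique": 0.15,
        "basal": 0.1,
        "default": 0
      },
      "gates": [
        {
          "power": 2,
          "inf_vhalf": -25,
          "inf_k": 6,
          "tau_type": "const",
          "tau": 4,
          "q10_tau_scale": 1
        }
      ]
    },
    {
      "name": "cat",
      "erev_mV": 0,
      "is_calcium": true,
      "density_mS_cm2": {
        "soma": 3,
        "apical_trunk": 1.5,
        "oblique": 0,
        "basal": 0,
        "default": 0
      },
      "gradient": {
        "regions": [
          "apical_trunk"
        ],
        "per_100um": -0.4,
        "min_factor": 0,
        "max_factor": 1
      },
      "gates": [
        {
          "power": 2,
          "inf_vhalf": -40,
          "inf_k": 6,
          "tau_type": "const",
          "tau": 5,
          "q10_tau_scale": 1
        },
        {
          "power": 1,
          "inf_vhalf": -65,
          "inf_k": -6.5,
          "tau_type": "bell",
          "tau": [
            15,
            60,
            -60,
            15,
            15
          ],
          "q10_tau_scale": 1
        }
      ]
    },
    {
      "name": "nap",
      "erev_mV": 55,
      "is_calcium": false,
      "density_mS_cm2": {
        "soma": 0.4,
        "apical_trunk": 0.28,
        "oblique": 0,
        "basal": 0,
        "default": 0
      },
      "gradient": {
        "regions": [
          "apical_trunk"
        ],
        "per_100um": -0.5,
        "min_factor": 0,
        "max_factor": 1
      },
      "gates": [
        {
          "power": 1,
          "inf_vhalf": -45,
          "inf_k": 5,
          "tau_type": "const",
          "tau": 10,
          "q10_tau_scale": 1
        }
      ]
    },
    {
      "name": "leak_dist",
      "erev_mV": -65,
      "is_calcium": false,
      "density_mS_cm2": {
        "apical_trunk": 0.05,
        "oblique": 0.05,
        "default": 0.0
      },
      "gradient": {
        "regions": [
          "apical_trunk",
          "oblique"
        ],
        "per_100um": 3.0,
        "min_factor": 0.0,
        "max_factor": 10.0
      },
      "gates": []
    }
  ],
  "shaft_calcium": {
    "enabled": true,
    "shell_depth_um": 0.1,
    "kappa": 20,
    "tau_ms": 20,
    "ca0_mM": 7e-05
  },
  "ltype_rule": {
    "mechanism": "cal",
    "proximal_um": 50
  }
}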