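[
  {
    "name": "Nax",
    "reversal": 50,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "m",
        "power": 3,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -38,
          "slope": -7,
          "tau_min": 0.025,
          "tau_amp": 0.15,
          "tau_vhalf": -38,
          "tau_slope": 12
        }
      },
      {
        "name": "h",
        "power": 1,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -47,
          "slope": 4,
          "tau_min": 0.3,
          "tau_amp": 3,
          "tau_vhalf": -47,
          "tau_slope": 12
        }
      }
    ]
  },
  {
    "name": "Na3",
    "reversal": 50,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "m",
        "power": 3,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -35,
          "slope": -7.2,
          "tau_min": 0.05,
          "tau_amp": 0.3,
          "tau_vhalf": -35,
          "tau_slope": 15
        }
      },
      {
        "name": "h",
        "power": 1,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -45,
          "slope": 4,
          "tau_min": 0.4,
          "tau_amp": 4,
          "tau_vhalf": -45,
          "tau_slope": 15
        }
      }
    ]
  },
  {
    "name": "KDR",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "n",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": 13,
          "vhalf_t": 13,
          "a0t": 0.12,
          "zeta_l": -3,
          "zeta_t": -3,
          "gmt": 0.7
        }
      }
    ]
  },
  {
    "name": "KAp",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "n",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": 11,
          "vhalf_t": 11,
          "a0t": 0.5,
          "zeta_l": -3,
          "zeta_t": -3,
          "gmt": 0.55
        }
      },
      {
        "name": "l",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -56,
          "vhalf_t": -56,
          "a0t": 0.02,
          "zeta_l": 3,
          "zeta_t": 3,
          "gmt": 0.5
        }
      }
    ]
  },
  {
    "name": "KAd",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "n",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -1,
          "vhalf_t": -1,
          "a0t": 0.2,
          "zeta_l": -3,
          "zeta_t": -3,
          "gmt": 0.39
        }
      },
      {
        "name": "l",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -56,
          "vhalf_t": -56,
          "a0t": 0.02,
          "zeta_l": 3,
          "zeta_t": 3,
          "gmt": 0.5
        }
      }
    ]
  },
  {
    "name": "KM",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "m",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -42,
          "vhalf_t": -42,
          "a0t": 0.008,
          "zeta_l": -4,
          "zeta_t": -4,
          "gmt": 0.1
        }
      }
    ]
  },
  {
    "name": "KD",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "n",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -33,
          "vhalf_t": -33,
          "a0t": 0.01,
          "zeta_l": -3,
          "zeta_t": -3,
          "gmt": 0.1
        }
      }
    ]
  },
  {
    "name": "CaN",
    "reversal": 120,
    "calcium_flux_fraction": 1,
    "gates": [
      {
        "name": "m",
        "power": 2,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -20,
          "slope": -7,
          "tau_min": 0.5,
          "tau_amp": 2,
          "tau_vhalf": -20,
          "tau_slope": 15
        }
      },
      {
        "name": "h",
        "power": 1,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -40,
          "slope": 8,
          "tau_min": 30,
          "tau_amp": 40,
          "tau_vhalf": -40,
          "tau_slope": 20
        }
      }
    ]
  },
  {
    "name": "CaL",
    "reversal": 120,
    "calcium_flux_fraction": 1,
    "gates": [
      {
        "name": "m",
        "power": 2,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -10,
          "slope": -6,
          "tau_min": 1,
          "tau_amp": 3,
          "tau_vhalf": -10,
          "tau_slope": 15
        }
      }
    ]
  },
  {
    "name": "CaT",
    "reversal": 120,
    "calcium_flux_fraction": 1,
    "gates": [
      {
        "name": "m",
        "power": 2,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -35,
          "slope": -6.5,
          "tau_min": 2,
          "tau_amp": 6,
          "tau_vhalf": -35,
          "tau_slope": 15
        }
      },
      {
        "name": "h",
        "power": 1,
        "form": "inf_tau",
        "parameters": {
          "vhalf": -60,
          "slope": 5,
          "tau_min": 15,
          "tau_amp": 40,
          "tau_vhalf": -60,
          "tau_slope": 15
        }
      }
    ]
  },
  {
    "name": "KCa",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "n",
        "power": 1,
        "form": "calcium_hill",
        "parameters": {
          "n": 2,
          "khalf_mM": 0.001,
          "tau_ms": 10
        }
      }
    ]
  },
  {
    "name": "Cagk",
    "reversal": -90,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "o",
        "power": 1,
        "form": "calcium_hill",
        "parameters": {
          "n": 2,
          "khalf_mM": 0.01,
          "tau_ms": 2,
          "vslope": 30,
          "vref": -20
        }
      }
    ]
  },
  {
    "name": "Ih",
    "reversal": -30,
    "calcium_flux_fraction": 0,
    "gates": [
      {
        "name": "l",
        "power": 1,
        "form": "borg_graham",
        "parameters": {
          "vhalf_l": -69.5,
          "vhalf_t": -64.1,
          "a0t": 0.0072,
          "zeta_l": 5.2,
          "zeta_t": 15.8,
          "gmt": 0.067,
          "clk": 1,
          "temperature_factor": 1,
          "kT": 0.0378
        }
      }
    ]
  }
]
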