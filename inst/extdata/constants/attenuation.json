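{
  "version": "1.0",
  "energy_keV": [60, 80, 100, 140, 170, 200, 300, 500, 800, 1000, 1400, 1700, 2000],
  "materials": {
    "water": {
      "density_g_cm3": 1,
      "mu_over_rho_cm2_g": [0.191395, 0.17672, 0.166664, 0.151906, 0.143337, 0.136126, 0.118227, 0.096681, 0.078548, 0.070606, 0.0595, 0.053587, 0.048926]
    },
    "pmma": {
      "density_g_cm3": 1.19,
      "mu_over_rho_cm2_g": [0.183236, 0.170563, 0.161358, 0.147393, 0.139162, 0.132201, 0.114861, 0.093941, 0.076326, 0.068609, 0.057817, 0.052072, 0.047543]
    },
    "bone": {
      "density_g_cm3": 1.85,
      "mu_over_rho_cm2_g": [0.224153, 0.183572, 0.164642, 0.14455, 0.134982, 0.127503, 0.110017, 0.089742, 0.072865, 0.065491, 0.055184, 0.049699, 0.045376]
    },
    "air": {
      "density_g_cm3": 0.0012,
      "mu_over_rho_cm2_g": [0.173027, 0.159306, 0.150077, 0.13668, 0.128942, 0.122442, 0.106328, 0.086946, 0.070639, 0.063496, 0.053508, 0.048191, 0.043999]
    },
    "agar": {
      "density_g_cm3": 1.02,
      "mu_over_rho_cm2_g": [0.191395, 0.17672, 0.166664, 0.151906, 0.143337, 0.136126, 0.118227, 0.096681, 0.078548, 0.070606, 0.0595, 0.053587, 0.048926]
    }
  },
  "collimator_materials": {
    "lead": {
      "density_g_cm3": 11.35,
      "energy_keV": [60, 80, 88, 88.005, 100, 150, 200, 300, 500, 800, 1000, 1500, 2000],
      "mu_over_rho_cm2_g": [5.021, 2.419, 1.91, 7.683, 5.549, 2.014, 0.9985, 0.4031, 0.1614, 0.0887, 0.07102, 0.05222, 0.04606]
    }
  }
}
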