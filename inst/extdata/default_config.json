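{
  "cohort": {
    "n_subjects": 10,
    "n_frames": 30,
    "seed": 1,
    "phases": {
      "t_es": 0.3733333333,
      "t_cross_endo": 0.53,
      "t_dd": 0.7,
      "t_ak": 0.9
    },
    "landmarks": {
      "asa": { "a_ed": 14.0, "a_es": 20.0, "a_dd": 16.0 },
      "vsa_endo": { "a_ed": 26.0, "a_es": 12.0, "a_dd": 23.7 },
      "vsa_epi": { "a_ed": 45.0, "a_es": 38.0, "a_dd": 41.4 }
    },
    "subject_sd": { "endo": 4.4, "epi": 7.3 }
  },
  "pressures": { "p_la_mmhg": 10, "p_lv_mmhg": 10, "equal_pressure": true },
  "driving_force": {
    "f_per_mass_mN_g": 25,
    "lv_mass_g": 125,
    "extra_min_g": 75,
    "extra_max_g": 275
  },
  "rig": {
    "a_small_m2": 0.002,
    "a_large_m2": 0.0027,
    "a_column_m2": 0.0005,
    "h0_m": 1.4,
    "rho_kg_m3": 1000,
    "g_m_s2": 9.81,
    "m_piston_kg": 0.5,
    "damping_N_s_m": 50,
    "travel_m": 0.03
  }
}
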