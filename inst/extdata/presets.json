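{
  "fig1": {
    "gene": {"k_g": 5, "gamma_g": 95, "k_m": 200, "gamma_m": 10,
             "k_p": 100, "gamma_p": 1}
  },
  "fig2": {
    "map": {"k_g": 5, "b_m": 2, "b_p": 10, "gamma_p": 1}
  },
  "fig3": {
    "fixed": {"k_m": 100, "gamma_g": 100, "gamma_m": 10, "gamma_p": 1},
    "k_g_values": [3, 10, 100],
    "b_p_values": [1, 10, 100]
  },
  "fig5": {
    "fixed": {"k_g": 5, "gamma_g": 100, "gamma_m": 10, "gamma_p": 1},
    "b_m_values": [1, 8, 30],
    "b_p_values": [1, 10, 100]
  },
  "fig6": {
    "network": {
      "upstream": {"k_g": 5, "gamma_g": 100, "k_m": 105, "gamma_m": 10,
                   "k_p": 10, "gamma_p": 1},
      "downstream": {"k_g": 5, "gamma_g": 100, "k_m": 200, "gamma_m": 10,
                     "k_p": 100, "gamma_p": 1},
      "K": 200, "n_H": 3, "k_l": 60
    },
    "b_m1_values": [1, 8, 30],
    "b_p1_values": [1, 10, 100]
  },
  "fig7": {
    "gene": {"k_g": 3, "gamma_g": 100, "k_m": 200, "gamma_m": 10,
             "k_p": 100, "gamma_p": 1},
    "kg_schedule": {"times": [7, 14], "values": [3, 30, 3]},
    "t_end": 21
  },
  "fig8": {
    "gene": {"k_g": 5, "gamma_g": 95, "k_m": 200, "gamma_m": 10,
             "k_p": 100, "gamma_p": 1},
    "tau": 0.03
  }
}
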