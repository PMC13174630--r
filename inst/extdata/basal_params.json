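{
  "format": "sansr-cell-params",
  "version": 1,
  "params": {
    "C_m": 32,
    "g_CaL": 0.464,
    "g_CaT": 0.1832,
    "g_Kr": 0.08113973,
    "g_Ks": 0.0259,
    "g_to": 0.252,
    "g_sus": 0.02,
    "g_if": 0.15,
    "g_st": 0.003,
    "g_bNa": 0.00486,
    "i_NaK_max": 2.88,
    "k_NCX": 0.00125,
    "d_NCX": 0.0001,
    "g_KACh": 0,
    "E_if_shift": 0,
    "P_up": 12,
    "K_up": 0.000286,
    "tau_dif_Ca": 0.04,
    "tau_tr": 40,
    "k_s": 250,
    "k_oCa": 10,
    "k_om": 0.06,
    "k_iCa": 0.5,
    "k_im": 0.005,
    "ec50_SR": 0.45,
    "max_SR": 15,
    "min_SR": 1,
    "h_SR": 2.5,
    "TC_tot": 0.031,
    "TMC_tot": 0.062,
    "CM_tot": 0.045,
    "CQ_tot": 10,
    "kf_TC": 88.8,
    "kb_TC": 0.446,
    "kf_TMC": 227.7,
    "kb_TMC": 0.00751,
    "kf_TMM": 2.277,
    "kb_TMM": 0.751,
    "kf_CM": 227.7,
    "kb_CM": 0.542,
    "kf_CQ": 0.534,
    "kb_CQ": 0.445,
    "Mg_i": 2.5,
    "V_i": 1.3467,
    "V_sub": 0.03328,
    "V_jSR": 0.0012,
    "V_nSR": 0.0408,
    "Na_i": 10,
    "Na_o": 140,
    "K_i": 140,
    "K_o": 5.4,
    "Ca_o": 2,
    "E_CaL": 40,
    "E_CaT": 45,
    "E_st": 37.4,
    "temperature": 310.15,
    "Km_fCa": 0.00035,
    "alpha_fCa": 0.021,
    "Km_Kp": 1.4,
    "Km_Nap": 14
  },
  "initial_state": {
    "V_m": -52.0323974783509,
    "d_L": 0.0016265471319239,
    "f_L": 0.472114721419316,
    "f_Ca": 0.662701007599488,
    "d_T": 0.0135389827824533,
    "f_T": 0.111075582714609,
    "pa_F": 0.2702856535371,
    "pa_S": 0.330314269606016,
    "pi_y": 0.79729945778824,
    "n": 0.0268165249130712,
    "q": 0.366600412818859,
    "r": 0.00858960692055187,
    "y": 0.0520589734904859,
    "q_a": 0.73356055969353,
    "q_i": 0.44010248985454,
    "Ca_i": 0.000116047102252271,
    "Ca_sub": 0.000117190848039106,
    "Ca_nSR": 24.9337128444858,
    "Ca_jSR": 20.7652141038601,
    "R_ryr": 0.959092313459881,
    "O_ryr": 3.98977434431772e-06,
    "I_ryr": 1.70152977589759e-07,
    "f_CMi": 0.0469886793196834,
    "f_CMs": 0.0471798496958354,
    "f_TC": 0.0228992388174668,
    "f_TMC": 0.422588993246263,
    "f_TMM": 0.509922149357295,
    "f_CQ": 0.961404420274312
  }
}
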