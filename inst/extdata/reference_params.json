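{
  "values": {
    "IGF1_0": 0,
    "Ins_0": 0,
    "IGF1R_0": 50000,
    "InsR_0": 40000,
    "IRS_0": 120000,
    "SOS_0": 30000,
    "Ras_0": 60000,
    "Raf_0": 40000,
    "MEK_0": 80000,
    "MAPK_0": 200000,
    "PI3K_0": 50000,
    "PDK1_0": 50000,
    "Akt_0": 120000,
    "TSC2_0": 40000,
    "mTORC1_0": 30000,
    "RPS6K_0": 80000,
    "kon_igf1": 1e-06,
    "koff_igf1": 0.05,
    "kphos_igf1": 1,
    "kdephos_igf1": 0.2,
    "kint_igf1": 0.05,
    "krec_igf1": 0.02,
    "kirs_igf1": 5e-05,
    "ksos_igf1": 6e-06,
    "kon_ins": 1e-06,
    "koff_ins": 0.1,
    "kphos_ins": 1,
    "kdephos_ins": 0.2,
    "kint_ins": 0.05,
    "krec_ins": 0.02,
    "kirs_ins": 8e-06,
    "ksos_ins": 6e-06,
    "k7": 3e-08,
    "kr_sos": 0.6,
    "k_ras": 2e-05,
    "kr_ras": 0.5,
    "k_raf": 1e-05,
    "kr_raf": 0.5,
    "k_mek": 1e-05,
    "kr_mek": 0.5,
    "k_mapk": 6e-06,
    "kr_mapk": 0.3,
    "k_pi3k": 8e-06,
    "kr_pi3k": 0.3,
    "k_pdk1": 1e-05,
    "kr_pdk1": 0.3,
    "k_akt": 1.5e-05,
    "kr_akt": 0.3,
    "k_tsc2": 1e-05,
    "kr_tsc2": 0.3,
    "k_mtorc1": 1.5e-05,
    "kr_mtorc1": 0.3,
    "k_s6k": 1.2e-05,
    "kr_s6k": 0.3,
    "kr_irs": 0.15,
    "kf203": 3e-06,
    "kf208": 3e-06,
    "kf_mapk_sos": 3e-08,
    "kf_mapk_irs": 3e-08,
    "k_ras_pi3k": 1e-09,
    "kf_akt_raf": 1e-09,
    "k_tsc2_mtorc1": 1e-06,
    "k_pdk1_s6k": 1e-09,
    "k_pi3k_ras": 1e-09,
    "k_lclear": 0.001,
    "kr_rint": 0.01
  },
  "bounds": {
    "kon_igf1": [1e-09, 0.1],
    "koff_igf1": [1e-06, 100],
    "kphos_igf1": [1e-06, 100],
    "kdephos_igf1": [1e-06, 100],
    "kint_igf1": [1e-06, 100],
    "krec_igf1": [1e-06, 100],
    "kirs_igf1": [1e-09, 0.1],
    "ksos_igf1": [1e-09, 0.1],
    "kon_ins": [1e-09, 0.1],
    "koff_ins": [1e-06, 100],
    "kphos_ins": [1e-06, 100],
    "kdephos_ins": [1e-06, 100],
    "kint_ins": [1e-06, 100],
    "krec_ins": [1e-06, 100],
    "kirs_ins": [1e-09, 0.1],
    "ksos_ins": [1e-09, 0.1],
    "k7": [1e-09, 0.1],
    "kr_sos": [1e-06, 100],
    "k_ras": [1e-09, 0.1],
    "kr_ras": [1e-06, 100],
    "k_raf": [1e-09, 0.1],
    "kr_raf": [1e-06, 100],
    "k_mek": [1e-09, 0.1],
    "kr_mek": [1e-06, 100],
    "k_mapk": [1e-09, 0.1],
    "kr_mapk": [1e-06, 100],
    "k_pi3k": [1e-09, 0.1],
    "kr_pi3k": [1e-06, 100],
    "k_pdk1": [1e-09, 0.1],
    "kr_pdk1": [1e-06, 100],
    "k_akt": [1e-09, 0.1],
    "kr_akt": [1e-06, 100],
    "k_tsc2": [1e-09, 0.1],
    "kr_tsc2": [1e-06, 100],
    "k_mtorc1": [1e-09, 0.1],
    "kr_mtorc1": [1e-06, 100],
    "k_s6k": [1e-09, 0.1],
    "kr_s6k": [1e-06, 100],
    "kr_irs": [1e-06, 100],
    "kf203": [1e-09, 0.1],
    "kf208": [1e-09, 0.1],
    "kf_mapk_sos": [1e-09, 0.1],
    "kf_mapk_irs": [1e-09, 0.1],
    "k_ras_pi3k": [1e-09, 0.1],
    "kf_akt_raf": [1e-09, 0.1],
    "k_tsc2_mtorc1": [1e-09, 0.1],
    "k_pdk1_s6k": [1e-09, 0.1],
    "k_pi3k_ras": [1e-09, 0.1],
    "k_lclear": [1e-06, 100],
    "kr_rint": [1e-06, 100],
    "IGF1_0": [0, 10000000],
    "Ins_0": [0, 10000000],
    "IGF1R_0": [1000, 1000000],
    "InsR_0": [1000, 1000000],
    "IRS_0": [1000, 1000000],
    "SOS_0": [1000, 1000000],
    "Ras_0": [1000, 1000000],
    "Raf_0": [1000, 1000000],
    "MEK_0": [1000, 1000000],
    "MAPK_0": [1000, 1000000],
    "PI3K_0": [1000, 1000000],
    "PDK1_0": [1000, 1000000],
    "Akt_0": [1000, 1000000],
    "TSC2_0": [1000, 1000000],
    "mTORC1_0": [1000, 1000000],
    "RPS6K_0": [1000, 1000000]
  }
}
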