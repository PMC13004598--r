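{
  "meta": {
    "version": "v1",
    "description": "Calibrated menstrual-cycle + circadian + PK parameter bundle (synthetic reconstruction)",
    "note": "baseline reconstructed and calibrated in-package; circadian and PK sections fitted to packaged synthetic series",
    "checksum": "8f5de9f91817f250956ba987d403caae"
  },
  "baseline": {
    "V0_LH": 191.731612512733,
    "V1_LH": 27465.4703797893,
    "Km_LH": 288.380978786907,
    "Ki_LH_P": 1.8630772230518,
    "k_LH": 0.563723202264116,
    "c_LH_P": 0.29355004607387,
    "c_LH_E": 0.00334599496214946,
    "a_LH": 14,
    "V_FSH": 411.209190520253,
    "Ki_FSH_Inh": 1.22693353904621,
    "w": 0.824323195614429,
    "k_FSH": 1.2,
    "c_FSH_P": 0.29921199566256,
    "c_FSH_E": 8.57929322089428e-06,
    "a_FSH": 8.21,
    "v": 2.5,
    "b": 0.0174589467242583,
    "c1": 0.0552352843127134,
    "c2": 0.0925583430920712,
    "c3": 0.005,
    "c4": 0.0123039335111109,
    "d1": 0.153160284263196,
    "d2": 7.87076750673203e-13,
    "k1": 0.694282340327962,
    "k2": 0.694282340327962,
    "k3": 0.590139989278768,
    "k4": 0.485997638229573,
    "alpha": 0.8,
    "beta": 0.02,
    "gamma": 0.02,
    "nu": 6,
    "e0": 63.2902748321437,
    "e1": 0.632902748321437,
    "e2": 4.21935165547625,
    "e3": 1.6877406621905,
    "p0": 0.786729316240064,
    "p1": 0.137677630342011,
    "p2": 0.137677630342011,
    "h0": 0.3,
    "h1": 0.0281486541846665,
    "h2": 0.0868766662460076,
    "h3": 0.0868766662460076,
    "k_Inh": 10.7806271892695,
    "tau": 2.56107712939861
  },
  "circadian": {
    "amplitude": {
      "LH": 0.3,
      "FSH": 0.15,
      "E2": 0.056131591920144,
      "P4": 0.149965033298124
    },
    "acrophase": {
      "LH": 0.55,
      "FSH": 0.58,
      "E2": 0.414126560111858,
      "P4": 0.617255799363205
    }
  },
  "rba": {
    "r1": 1.7,
    "r2": 0.01
  },
  "pk": {
    "EE": {
      "F": 1,
      "Vc": 135.25266008334,
      "ka": 30,
      "k21": 3,
      "alpha1": 8,
      "beta1": 1.27965633334144,
      "conc_scale": 1000
    },
    "DNG": {
      "F": 1,
      "Vc": 14.2766696754637,
      "ka": 20,
      "k21": 3,
      "alpha1": 6,
      "beta1": 1.75110866667776,
      "conc_scale": 1
    }
  },
  "initial_conditions": {
    "RP_LH": 198.086447257641,
    "LH": 3.15465500407277,
    "RP_FSH": 96.8075867191303,
    "FSH": 6.75830272342314,
    "RcF": 1.01997532544088,
    "GrF": 0.824018579720706,
    "DomF": 4.21493462336922,
    "Lut1": 0.00149288155450769,
    "Lut2": 0.0159126417490274,
    "Lut3": 0.156020035818723,
    "Lut4": 1.02749212087681,
    "Inh": 0.52376432776716
  },
  "threshold": 3
}
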