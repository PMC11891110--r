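{
  "vertebra_C1": 1,
  "vertebra_C2": 2,
  "vertebra_C3": 3,
  "vertebra_C4": 4,
  "vertebra_C5": 5,
  "vertebra_C6": 6,
  "vertebra_C7": 7,
  "vertebra_T1": 8,
  "vertebra_T2": 9,
  "vertebra_T3": 10,
  "vertebra_T4": 11,
  "vertebra_T5": 12,
  "vertebra_T6": 13,
  "vertebra_T7": 14,
  "vertebra_T8": 15,
  "vertebra_T9": 16,
  "vertebra_T10": 17,
  "vertebra_T11": 18,
  "vertebra_T12": 19,
  "vertebra_L1": 20,
  "vertebra_L2": 21,
  "vertebra_L3": 22,
  "vertebra_L4": 23,
  "vertebra_L5": 24,
  "sacrum": 25,
  "ilium_left": 26,
  "ilium_right": 27,
  "spinal_cord": 28,
  "rib_left_1": 31,
  "rib_left_2": 32,
  "rib_left_3": 33,
  "rib_left_4": 34,
  "rib_left_5": 35,
  "rib_left_6": 36,
  "rib_left_7": 37,
  "rib_left_8": 38,
  "rib_left_9": 39,
  "rib_left_10": 40,
  "rib_left_11": 41,
  "rib_left_12": 42,
  "rib_right_1": 43,
  "rib_right_2": 44,
  "rib_right_3": 45,
  "rib_right_4": 46,
  "rib_right_5": 47,
  "rib_right_6": 48,
  "rib_right_7": 49,
  "rib_right_8": 50,
  "rib_right_9": 51,
  "rib_right_10": 52,
  "rib_right_11": 53,
  "rib_right_12": 54,
  "femur_left": 55,
  "femur_right": 56,
  "liver": 57,
  "aorta": 58
}
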