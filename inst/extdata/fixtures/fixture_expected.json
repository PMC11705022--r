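{
  "n_y1_rows": 59,
  "n_y2_rows": 58,
  "n_ambiguous_y1": 2,
  "n_ambiguous_y2": 0,
  "n_unmatched_y1": 3,
  "n_unmatched_y2": 4,
  "n_matched": 54,
  "n_after_category_WX": 52,
  "n_after_invalid_price": 50,
  "n_after_incomplete_nutrition": 47,
  "n_after_fsanz_ineligible": 44,
  "sodium_groups": {
    "large_decrease": 1,
    "medium_decrease": 1,
    "little_change": 43,
    "medium_increase": 1,
    "large_increase": 1
  },
  "sugars_groups": {
    "large_decrease": 1,
    "medium_decrease": 0,
    "little_change": 46,
    "medium_increase": 0,
    "large_increase": 0
  },
  "sodium_contingency": {
    "multinational": [1, 43],
    "private_label_premium": [1, 0],
    "private_label_discount": [1, 0],
    "domestic_or_other": [1, 0]
  },
  "fsanz_category_counts": {
    "cat1_beverages": 4,
    "cat2_other": 38,
    "cat3_cheese_fats_oils": 2
  },
  "scores": {
    "P01": [6, 2],
    "P02": [6, 4],
    "P03": [6, 8],
    "P04": [6, 8],
    "P05": [6, 8],
    "P06": [4, 0],
    "P07": [2, 2],
    "P08": [0, 0],
    "P09": [2, 0],
    "P10": [0, 0],
    "P11": [38, 38],
    "P12": [27, 27],
    "P13": [21, 21],
    "P14": [-7, -7],
    "P15": [-2, -2],
    "P16": [-2, -2],
    "P17": [-2, -2],
    "P18": [-2, -2],
    "P19": [-2, -2],
    "P20": [-2, -2],
    "P21": [-2, -2],
    "P22": [-2, -2],
    "P23": [-2, -2],
    "P24": [-2, -2],
    "P25": [-2, -2],
    "P26": [-2, -2],
    "P27": [-2, -2],
    "P28": [-2, -2],
    "P29": [-2, -2],
    "P30": [-2, -2],
    "P31": [-2, -2],
    "P32": [-2, -2],
    "P33": [-2, -2],
    "P34": [-2, -2],
    "P35": [-2, -2],
    "P36": [-2, -2],
    "P37": [-2, -2],
    "P38": [-2, -2],
    "P39": [-2, -2],
    "P40": [-2, -2],
    "P41": [-2, -2],
    "P42": [-2, -2],
    "P43": [-2, -2],
    "P52": [-2, -2]
  }
}
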