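{
  "version": "fsanz-npsc-schedule/transcription-1",
  "notes": [
    "Point schedules for the FSANZ Nutrient Profiling Scoring Criterion, transcribed",
    "into data so the scorer is table-driven and the file can be revised when the",
    "standard is. Each step is [threshold, points]; points are awarded when the",
    "per-100 g (or ml) value is >= threshold (the standard prints strict '>' band",
    "edges; the inclusive convention differs only on a measure-zero set and makes a",
    "value equal to a printed band edge earn that band's points).",
    "Category 3 foods (cheese >320 mg calcium/100 g, edible oils, spreads, margarine,",
    "butter) use extended saturated-fat and sodium ladders up to 30 points; the",
    "extended sodium ladder is encoded as 90x the saturated-fat ladder (the",
    "schedules' shared geometric progression). Energy and sugars cap at 10 points in",
    "every category. fvnl is the fruit/vegetable/nut/legume percentage (V points,",
    "non-concentrated); protein points are withheld when baseline points reach the",
    "gate unless V points reach the exemption level."
  ],
  "kj_per_kcal": 4.184,
  "pass_below": {
    "cat1_beverages": 1,
    "cat2_other": 4,
    "cat3_cheese_fats_oils": 28
  },
  "protein_gate": {
    "baseline_trigger": 13,
    "v_points_exempt": 5
  },
  "baseline": {
    "energy_kj": {
      "steps": [[335, 1], [670, 2], [1005, 3], [1340, 4], [1675, 5],
                [2010, 6], [2345, 7], [2680, 8], [3015, 9], [3350, 10]],
      "cat3_steps": null
    },
    "satfat_g": {
      "steps": [[1, 1], [2, 2], [3, 3], [4, 4], [5, 5],
                [6, 6], [7, 7], [8, 8], [9, 9], [10, 10]],
      "cat3_steps": [[1, 1], [2, 2], [3, 3], [4, 4], [5, 5],
                     [6, 6], [7, 7], [8, 8], [9, 9], [10, 10],
                     [11.2, 11], [12.5, 12], [13.9, 13], [15.5, 14], [17.3, 15],
                     [19.3, 16], [21.6, 17], [24.1, 18], [26.9, 19], [30, 20],
                     [33.5, 21], [37.4, 22], [41.7, 23], [46.6, 24], [52, 25],
                     [58, 26], [64.7, 27], [72.3, 28], [80.6, 29], [90, 30]]
    },
    "sugars_g": {
      "steps": [[4.5, 1], [9, 2], [13.5, 3], [18, 4], [22.5, 5],
                [27, 6], [31, 7], [36, 8], [40, 9], [45, 10]],
      "cat3_steps": null
    },
    "sodium_mg": {
      "steps": [[90, 1], [180, 2], [270, 3], [360, 4], [450, 5],
                [540, 6], [630, 7], [720, 8], [810, 9], [900, 10]],
      "cat3_steps": [[90, 1], [180, 2], [270, 3], [360, 4], [450, 5],
                     [540, 6], [630, 7], [720, 8], [810, 9], [900, 10],
                     [1008, 11], [1125, 12], [1251, 13], [1395, 14], [1557, 15],
                     [1737, 16], [1944, 17], [2169, 18], [2421, 19], [2700, 20],
                     [3015, 21], [3366, 22], [3753, 23], [4194, 24], [4680, 25],
                     [5220, 26], [5823, 27], [6507, 28], [7254, 29], [8100, 30]]
    }
  },
  "modifying": {
    "fvnl_pct": {
      "steps": [[40, 1], [60, 2], [100, 5]]
    },
    "protein_g": {
      "steps": [[1.6, 1], [3.2, 2], [4.8, 3], [6.4, 4], [8, 5]]
    },
    "fibre_g": {
      "steps": [[0.9, 1], [1.9, 2], [2.8, 3], [3.7, 4], [4.7, 5]]
    }
  },
  "category_mapping": {
    "cat1_tra": ["B"],
    "cat3_tra": ["H"],
    "cheese_tra": ["D"],
    "cheese_calcium_above_mg_per100": 320
  }
}
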