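{
  "version": "1.0",
  "description": "Canonical 33-variable Action Unit space and recoding scheme from generative AU labels (compound, unilateral, bilateral) to independent canonical variables.",
  "canonical": ["1", "2L", "2R", "4", "5", "6L", "6R", "7L", "7R", "9",
                "10L", "10R", "11L", "11R", "12L", "12R", "13", "14L", "14R", "15",
                "16", "17", "20L", "20R", "22", "23", "24", "25", "26", "27",
                "38", "39", "43"],
  "lateralized": [2, 6, 7, 10, 11, 12, 14, 20],
  "compounds": {
    "1+2": [1, 2],
    "6+12": [6, 12],
    "12+25": [12, 25]
  },
  "vocabulary": {
    "note": "Default generative vocabulary of the simulator: 42 labels (3 compound, 14 unilateral, 25 bilateral). Declared stand-in for the original generator's 42-label set, which is not printed in full; the unilateral pair 11L/11R is omitted to match the reported size while keeping every canonical variable reachable.",
    "compound": ["1+2", "6+12", "12+25"],
    "unilateral": ["2L", "2R", "6L", "6R", "7L", "7R", "10L", "10R",
                   "12L", "12R", "14L", "14R", "20L", "20R"],
    "bilateral": [1, 2, 4, 5, 6, 7, 9, 10, 11, 12, 13, 14, 15, 16, 17,
                  20, 22, 23, 24, 25, 26, 27, 38, 39, 43]
  }
}
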