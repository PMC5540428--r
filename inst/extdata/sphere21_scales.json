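{
  "anxiety_depression": {
    "name": "anxiety_depression",
    "items": ["2", "3", "5", "12", "20", "21", "23", "26", "27", "28", "30", "32", "33", "34"],
    "provenance": {
      "2": "original (Irritable/cranky; most discriminant)",
      "3": "original (Poor memory; least discriminant; shared with chronic fatigue)",
      "5": "original (Nervous/tense; tail-only IRSF decrease, retained)",
      "12": "original (Unhappy/depressed)",
      "20": "original (Under strain)",
      "21": "original (item number reconstructed, not stated in running text)",
      "23": "original (Frustrated; among the easiest)",
      "26": "original (Annoyed easily; among the easiest)",
      "27": "original (Everything on top of you)",
      "28": "original (Dizziness; most difficult)",
      "30": "original (Poor concentration; shared with chronic fatigue)",
      "32": "original (Feeling lost for words; shared with chronic fatigue)",
      "33": "original (Losing confidence; max sex DIF 0.23, retained)",
      "34": "original (item number reconstructed, not stated in running text)"
    }
  },
  "chronic_fatigue": {
    "name": "chronic_fatigue",
    "items": ["3", "7", "15", "17", "22", "25", "29", "30", "31", "32"],
    "provenance": {
      "3": "original (Poor memory; shared with anxiety-depression)",
      "7": "original (Waking up tired)",
      "15": "added (Back pain; moderately discriminant)",
      "17": "original (Tired after activity; among the steepest IRSF)",
      "22": "added (Weak muscles; most difficult in scale)",
      "25": "original",
      "29": "original (Tired after rest; among the steepest IRSF)",
      "30": "original (Poor concentration; shared with anxiety-depression)",
      "31": "original (Tired after activity)",
      "32": "original (Feeling lost for words; shared with anxiety-depression)",
      "1": "excluded:sex_dif (Headaches; DIF 0.26 with non-overlapping bands)",
      "14": "excluded:low_endorsement (Fevers; step function ceiling below 0.4)",
      "24": "excluded:low_endorsement (Diarrhoea/constipation)",
      "6": "excluded:non_monotone",
      "10": "excluded:non_monotone",
      "16": "excluded:non_monotone (Longer sleep)",
      "13": "excluded:low_endorsement"
    }
  }
}
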