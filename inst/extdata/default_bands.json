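{
  "normal": {
    "ranges": {
      "P1": {
        "n_pairs": [11, 14],
        "top_sum": [0.35, 0.46]
      },
      "P2": {
        "n_pairs": [0, 3],
        "top_sum": [0, 1]
      }
    },
    "freq_bpm": [55, 95],
    "max_prob_rule": {
      "type": "all_below",
      "threshold": 0.3
    }
  },
  "chronic": {
    "ranges": {
      "P1": {
        "n_pairs": [21, 31],
        "top_sum": [0.35, 0.48]
      },
      "P2": {
        "n_pairs": [10, 14],
        "top_sum": [0.54, 0.7]
      }
    },
    "freq_bpm": [65, 105],
    "max_prob_rule": {
      "type": "any_at_or_above",
      "threshold": 0.3
    }
  },
  "acute": {
    "ranges": {
      "P1": {
        "n_pairs": [9, 11],
        "top_sum": [0.5, 0.6]
      },
      "P2": {
        "n_pairs": [3, 6],
        "top_sum": [0.46, 0.75]
      }
    },
    "freq_bpm": [75, 100],
    "max_prob_rule": {
      "type": "any_at_or_above",
      "threshold": 0.3
    }
  },
  "pacemaker": {
    "ranges": {
      "P1": {
        "n_pairs": [4, 5],
        "top_sum": [0.5, 0.6]
      },
      "P2": {
        "n_pairs": [2, 2],
        "top_sum": [1, 1]
      }
    },
    "freq_bpm": [60, 75],
    "max_prob_rule": {
      "type": "any_at_or_above",
      "threshold": 0.3
    }
  }
}
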