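[
  {
    "name": "Sedlo",
    "activities": [
      "longline_pelagic"
    ],
    "score": 2.6
  },
  {
    "name": "Condor",
    "activities": [
      "hook_and_line",
      "longline_bottom",
      "longline_pelagic"
    ],
    "score": 3.6
  },
  {
    "name": "Rosemary",
    "activities": [
      "gillnet_bottom",
      "longline_bottom",
      "longline_pelagic",
      "pots_traps",
      "trawl_bottom",
      "trawl_midwater"
    ],
    "score": 5
  },
  {
    "name": "Anton Dohrn",
    "activities": [
      "longline_bottom",
      "pots_traps",
      "trawl_bottom"
    ],
    "score": 3.6
  },
  {
    "name": "Josephine",
    "activities": [
      "gillnet_bottom",
      "longline_bottom",
      "longline_pelagic",
      "trawl_bottom",
      "trawl_midwater"
    ],
    "score": 5
  },
  {
    "name": "Gorringe",
    "activities": [
      "longline_bottom",
      "pots_traps",
      "purse_seine",
      "trawl_bottom",
      "trawl_midwater"
    ],
    "score": 4.6
  },
  {
    "name": "Bowie",
    "activities": [
      "hook_and_line",
      "longline_bottom",
      "pots_traps"
    ],
    "score": 2.4
  },
  {
    "name": "Cobb",
    "activities": [
      "gillnet_bottom",
      "longline_bottom",
      "pots_traps",
      "trawl_midwater"
    ],
    "score": 2.6
  },
  {
    "name": "pelagic_longline_only",
    "activities": [
      "longline_pelagic"
    ],
    "score": 2.6
  }
]
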