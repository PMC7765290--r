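{
  "name": "PsAMRIS",
  "joints": ["MCP2", "MCP3", "MCP4", "MCP5", "PIP2", "PIP3", "PIP4", "PIP5", "DIP2", "DIP3", "DIP4", "DIP5"],
  "sites_per_joint": 2,
  "features": [
    {
      "feature": "synovitis",
      "score_min": 0,
      "score_max": 3
    },
    {
      "feature": "flexor_tenosynovitis",
      "score_min": 0,
      "score_max": 3
    },
    {
      "feature": "periarticular_inflammation",
      "score_min": 0,
      "score_max": 1
    },
    {
      "feature": "bone_edema",
      "score_min": 0,
      "score_max": 3
    },
    {
      "feature": "bone_erosion",
      "score_min": 0,
      "score_max": 10
    },
    {
      "feature": "bone_proliferation",
      "score_min": 0,
      "score_max": 1
    }
  ]
}
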