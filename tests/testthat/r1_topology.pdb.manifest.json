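{
  "subcommand": "simulate",
  "parameters": {
    "seed": 5
  },
  "inputs": {
    "recipe": {
      "path": "/tmp/RtmpoPZZo2/cli4c764ebfb18/recipe.json",
      "md5": "89e59eb1b6aa4a9a1c2df0551fc9ac0f"
    }
  }
}
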