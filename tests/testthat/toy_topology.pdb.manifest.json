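{
  "subcommand": "simulate",
  "parameters": {
    "seed": 17
  },
  "inputs": {
    "recipe": {
      "path": "/tmp/RtmpoPZZo2/cli4c771ff3f31/recipe.json",
      "md5": "d671bf7f84d8781fe8f9f8e34372efa4"
    }
  }
}
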