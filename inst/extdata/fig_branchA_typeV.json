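{
  "name": "duplication pathway to the type V hotspot",
  "start": ["P", "CR", "F"],
  "events": [
    {"block": [1, 3], "losses": [1]},
    {"block": [4, 5], "losses": [2, 4, 7]}
  ],
  "end": ["CR", "P", "F", "CR"]
}
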