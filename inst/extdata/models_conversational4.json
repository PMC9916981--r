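{
  "version": "1.0",
  "task": "conversational4",
  "categories": ["bored", "confused", "interested", "thinking"],
  "notation": "Same notation as the basic6 registry. Configurations for these five published studies are not bundled; supply them as spec strings or explicit AU lists to use a slot. A model may cover any subset of the four categories.",
  "models": [
    { "name": "Cunningham et al. (2005)", "categories": {} },
    { "name": "Ekman (1979)", "categories": {} },
    { "name": "conversational study 3 (name unavailable)", "categories": {} },
    { "name": "el Kaliouby & Robinson (2005)", "categories": {} },
    { "name": "conversational study 5 (name unavailable)", "categories": {} }
  ]
}
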