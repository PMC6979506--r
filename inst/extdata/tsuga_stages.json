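{
  "stage_labels": ["<5.0cm", "5.0-12.5cm", "12.5-22.5cm", "22.5-32.5cm", "32.5-42.5cm", ">42.5cm"],
  "alpha": 1
}
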