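{
  "seed": 1,
  "out": "musemap-demo",
  "simulate": {"shape": [12, 12, 8], "snr": 4},
  "decode": {"k": 200, "targets": ["song", "genre"]},
  "searchlight": {"kinds": ["melody_rel"], "repetitions": 5}
}
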