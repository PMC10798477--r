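{
  "file": "ctm-b2-d12-m4.tsv",
  "md5": "cd797ce9582cff6c236df71b2cb20d06",
  "entries": 8190,
  "stored_rows": 4095,
  "source_label": "randser exhaustive (4,2) Turing-machine enumeration (cap 107 steps), two-split completion",
  "n_states": 4,
  "total_halting": 5970768960,
  "note": "Computed by randser::ctm_enumerate(4) / ctm_build_table(); not the published (5,2) machine table."
}
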