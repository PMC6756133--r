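{
  "alpha": -8.03,
  "beta": 1.773,
  "comment": "Reference logistic psychometric parameters for the simulated behavioral study: alpha is the speech reception threshold in dB SNR, beta the spread in dB (slope 100/(4*beta) = 14.1 %/dB)."
}
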