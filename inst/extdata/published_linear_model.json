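{
  "description": "Published 5-variable linear SVM for steroid-resistant nephrotic syndrome: score = 0.2527 - 0.4493*L% - 0.7948*N% - 0.2683*ALB + 0.2879*C4 + 0.0925*Vcl on standardized inputs; class = sign(score), +1 = SRNS. Read-only fixture for formula-evaluation tests; the original standardization constants are not published, so this is not a clinical predictor.",
  "label_convention": {"positive": "SRNS", "negative": "SSNS"},
  "intercept": 0.2527,
  "linear_coefs": {
    "L%": -0.4493,
    "N%": -0.7948,
    "ALB": -0.2683,
    "C4": 0.2879,
    "Vcl": 0.0925
  }
}
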