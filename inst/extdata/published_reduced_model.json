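{
  "description": "Published reduced 8-variable SVM for steroid-resistant nephrotic syndrome: two linear terms (N%, Vcl) plus six 4th-order B-spline blocks (ESR, u-OB, IgA, CHOL, AST, prolonged PT). Read-only fixture for formula-evaluation tests; the original spline domains and standardization constants are not published, so the spline blocks can only be evaluated as supplied basis contributions (or zeroed).",
  "label_convention": {"positive": "SRNS", "negative": "SSNS"},
  "intercept": 0.440,
  "linear_coefs": {
    "N%": -0.1516,
    "Vcl": 0.0845
  },
  "spline_order": 4,
  "spline_coefs": {
    "ESR": [-0.1802, 2.8125, 0.8125, 0.5181],
    "u-OB": [1.9623, -2.5043, 2.3149, -0.4819],
    "IgA": [1.9071, -4.0454, 2.4880, -0.5299],
    "CHOL": [-0.8849, -2.2604, 1.5635, -0.5050],
    "AST": [3.2336, -4.3389, 3.1936, 1.2667],
    "prolonged PT": [-3.6318, 1.8816, -1.2195, -1.9774]
  }
}
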