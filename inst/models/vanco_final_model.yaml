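structure: 2cmt
theta:
  V1: 1.27
  V2: 2.422
  CL: 0.42
  Q: 1.161
effects:
- param: CL
  covariate: bbw
  exponent: 0.888
  type: power
  ref: 3.22
- param: CL
  covariate: pna
  exponent: 0.449
  type: power
  ref: 29.0
iiv:
  CL: 0.317
residual:
  type: additive
  stdev0: 2.187
  cv: 0.0
infusion_default: 1.0
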