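schema: plenoscope-sidecar-1
optics:
  objectiveMagnification: 20.0
  objectiveNA: 0.75
  mlaPitch: 100.0
  pixelsPerLens: 15
  lensesPerTile: 140
  totalMagnification: 32.25806451612903
  refractiveIndex: 1.0
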