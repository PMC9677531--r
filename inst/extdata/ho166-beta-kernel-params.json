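{
  "version": "1.0",
  "nuclide": "Ho-166",
  "maxRangeMm": 8.5,
  "r0": 0.75,
  "power": 2,
  "notes": "Synthetic parametric radial beta kernel: energy density g(r) ~ r^power * exp(-r/r0), renormalized over [0, maxRangeMm]. Not a Monte Carlo tabulation; constants chosen so the maximum range matches the ~8.5 mm maximum beta range of Ho-166 in soft tissue and ~90% of energy is absorbed within ~4 mm. Override with a tabulated CSV kernel for scanner/medium-specific work."
}
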