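# Benzene biofiltration parameter set (literature values used by the bundled
# steady-state validation benchmark).
compound:
  henry: 0.23          # dimensionless Henry's constant Cg/Cl
  mu_max: 0.68         # maximum specific growth rate
  mu_max_units: 1/h
  K: 12.22             # Monod half-saturation constant, g/m3
  yield: 0.708         # yield coefficient
  Dw: 1.04e-9          # aqueous diffusivity, m2/s
biofilm:
  density: 100.0       # Xv, kg/m3
  area: 40.0           # As, biofilm area per bed volume, 1/m
  thickness: 5.0e-5    # delta, m
bed:
  height: 1.5          # m
  n_segments: 10
  void_fraction: 0.35  # not part of the benchmark; steady state independent of it
  ebrt: 60.0           # s (velocity derived as height/ebrt)
  inlet: 0.13          # g/m3
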