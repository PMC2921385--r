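# "basic" parameter set: taproot-like behaviour (soft auxin-dependent
# inhibition of PIN1 expression, h2 = 6, q3 = 2 cu).
#
# Provenance: re-estimated for this package by coordinatewise calibration of
# the 1D minimal model (N = 50) against the published in-text landmarks of
# the reflected-flow system — a stable stationary distal maximum in cell 5
# at influx alpha = 1 that tolerates single-cell auxin fluctuations below
# 4 cu, a proximal march of the maximum and loss of stability as alpha
# grows, twin tip/base maxima once K0 drops below 0.05, and a bimodal
# mitotic-activity profile with quiescent-centre suppression. The original
# published table of values is not distributed with this package.
# Units: concentrations in cu, time in tu, cell size in length units.
name: basic
transport:
  alpha: 1.0     # influx from the shoot into cell N (cu/tu)
  Kd: 0.02       # auxin degradation (1/tu)
  D: 0.5         # auxin diffusion (1/tu)
  K0: 0.1        # active transport (1/(cu*tu))
  k1: 1.0        # PIN1 synthesis rate constant (cu/tu)
  q1: 0.5        # PIN1 synthesis activation threshold (cu)
  q2: 5.0        # PIN1 synthesis saturation threshold (cu)
  h1: 2          # PIN1 synthesis exponent
  k2: 0.05       # basal PIN1 degradation (1/tu)
  q3: 2.0        # auxin threshold of PIN1 degradation (cu)
  h2: 6          # PIN1 degradation exponent
divf:
  beta: 1.0      # maximal Division Factor synthesis (cu/tu)
  T: 0.1         # sigmoid scale of gradient-driven synthesis (cu)
  kdeg: 0.06     # basal Division Factor degradation (1/tu)
  q4: 2.4        # lower auxin threshold of degradation response (cu)
  q5: 3.5        # upper auxin threshold of degradation response (cu)
  h3: 6
  h4: 6
  D_DivF: 0.5    # Division Factor diffusion (1/tu)
cycle:
  K_growth: 0.01 # elongation rate (length/tu)
  r_min: 2.0     # minimal division size (length)
  r0: 1.0        # daughter birth size (length)
  gp_rate: 0.1   # growth-phase completion hazard scale (1/tu)
  gp_exp: 20     # growth-phase completion sharpness
  ip_rate: 0.1   # idle-phase completion hazard scale (1/tu)
  ip_mid: 1.2    # Division Factor level of peak division activity (cu)
  ip_hup: 2      # rising exponent of the bell-shaped response
  ip_hdown: 6    # falling exponent of the bell-shaped response
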