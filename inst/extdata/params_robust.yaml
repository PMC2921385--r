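# "robust" parameter set: fibrous-root-like behaviour — sharply thresholded
# auxin-dependent inhibition of PIN1 expression (h2 = 10 at q3 = 3.26 cu;
# these two values are published in-text anchors and are asserted at load).
# The remaining transport values are re-estimated as for the basic set (see
# params_basic.yaml); Division Factor and cell-cycle parameters are shared
# with the basic set.
name: robust
transport:
  alpha: 1.0
  Kd: 0.015
  D: 1.0
  K0: 0.1
  k1: 1.0
  q1: 0.5
  q2: 5.0
  h1: 2
  k2: 0.05
  q3: 3.26     # anchor: threshold of auxin-dependent PIN1 degradation
  h2: 10       # anchor: pronounced inhibition above q3
divf:
  beta: 1.0
  T: 0.1
  kdeg: 0.06
  q4: 2.4
  q5: 3.5
  h3: 6
  h4: 6
  D_DivF: 0.5
cycle:
  K_growth: 0.01
  r_min: 2.0
  r0: 1.0
  gp_rate: 0.1
  gp_exp: 20
  ip_rate: 0.1
  ip_mid: 1.2
  ip_hup: 2
  ip_hdown: 6
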