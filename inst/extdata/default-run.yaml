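# Standard operating point of the reoptimization model. Any key omitted
# falls back to the same defaults; unknown keys are rejected.
arm:
  m_sh: 1.4
  m_el: 1.1
  l_sh: 0.3
  l_el: 0.33
  s_sh: 0.11
  s_el: 0.16
  I_sh: 0.025
  I_el: 0.045
  nu: 0.05
  g_sh: 2
  g_el: 1
field:
  phi: 2
  psi: 90
ofc:
  T_H: 0.28
  T_G: 0.13
  delta: 0.01
  w_u: 1.0e-5
  boundary: p
  delay: 0.12
  sigma_w: 1
  sigma_xi: 1
  estMode: delay
  duration: 1.0
viaPoints:
  fractions: [0.32, 0.64, 0.96]
  offsets: [0.0, 0.0, 0.0]
seed: 1
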