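# Reference configuration: four-whorled phyllotaxis (eta = 0.3902).
# Physical defaults: grid 40x40x60, dx = 1, dt1 = 5e-2, dt2 = 1e-5 (ratio
# 5000); BVAM kinetics a = 1.1123, b = -1.0122, h = -1, D = 0.516, c = 0.57;
# surface tensions rho_phi = 2.5, rho_u = 0.5; D_phi = 1, m = 15; dome
# R = 10, Hz = 6; tip Gaussian width R/2, kappa = 2; beta = 0.5, gamma = 0.2.
bvam:
  eta: 0.3902
  c: 0.57
mech:
  beta: 0.5
  gamma: 0.2
  kappa: 2
  g_width: 5
sched:
  max_cycles: 40
  stop_after_first_gen: yes
seed: 1
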