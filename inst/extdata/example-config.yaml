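# Example configuration. Omitted keys fall back to the reference defaults
# (sigma_K = 1, sigma = 0.5, dt = 1e-2, split 1e-3 every 10, merge 1e-1,
# extinction cutoff 1e-6, grid 0.05..2 by 0.05, 30 replicas, K0 = 1e3,
# sigma_mu = 0.003).
model:
  D: 2
  sigma: 0.5

schedule:
  record_every: 1

experiment:
  n_replicas: 10
  V_C_grid: [0.1, 0.4, 0.8, 1.2, 2.0]
  seed: 1

ibm:
  K0: 1000
  sigma_mu: 0.003
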