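# Standard two-task regime-comparison configuration: fast bounded gates
# (tau_c << tau_w) on a blocked curriculum of two orthogonal teachers.
model:
  p: 2
  d_in: 32
  d_out: 8
  tau_w: 1.3
  tau_c: 0.03
  lambda_norm: 1.0
  lambda_nonneg: 1.0
  norm_order: 1
  gate_mode: scalar
  sigma0: 0.01
curriculum:
  m: 2
  block_length: 1.0
  n_blocks: 30
  sampling: expectation
  batch_size: 32
integration: {}
seeds:
  init: 1
  data: 1
  teachers: 1
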