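# shared fixture builders (all generated in code)

std_grid <- function(n = 162, dt = 1.24) uniform_curve(numeric(n), dt = dt)

std_aif <- function(grid = std_grid()) gamma_variate_aif(grid)

# noiseless tissue curve for a clinical CBF (ml/100 g/min) at CBV 4%
clean_ctc <- function(cbf_clin, grid = std_grid(), cbv = 0.04, lam = 1,
                      aif = std_aif(grid)) {
  cbf <- cbf_clin / 6000
  forward_model(aif, gamma_residue(lam, cbv / cbf, grid), cbf)
}
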