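## Shared fixtures: the standard probe/protocol of the study conditions
## (10 mM oxidized probe, -0.6..+0.1 V window, 100 mV/s, 10 mV steps)
## plus coarser fast variants for tests where numerical accuracy is not
## the point.

std_couple <- function() redox_couple(c_b = 1e-5, E_f0 = -0.25, T_K = 298)

std_protocol <- function(v = 0.1, ...) cv_protocol(v = v, ...)

std_grid <- function(D = 1e-5, n = 500L, protocol = std_protocol())
  make_grid(domain_length(D, protocol), n)

## coarse grid + few substeps: ~4x faster, ~percent-level accuracy
fast_sim <- function(interface, couple = std_couple(),
                     protocol = std_protocol(), n = 200L, substeps = 4L)
  simulate_cv(interface, couple, protocol,
              make_grid(domain_length(interface$D, protocol), n),
              substeps_per_Estep = substeps)

bare_params <- function() interface_params(D = 1e-5, k0 = 4.5e-3,
                                           alpha = 0.5, ECSA = 0.1256)

randles_sevcik <- function(A, D, c_b, v) 2.69e5 * A * sqrt(D) * c_b * sqrt(v)
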