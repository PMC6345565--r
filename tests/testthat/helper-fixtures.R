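# Shared fixtures: the published PICK1 simulation parameter set and a small
# random-parameter generator for property-style checks.

fig_params <- function(...) pick1_parameters(...)

random_params <- function() {
  rate_parameters(k1 = 10^stats::runif(1, 3, 7),
                  k_off = 10^stats::runif(1, -4, 0),
                  r = stats::runif(1, 50, 500),
                  f = 10^stats::runif(1, 0, 3))
}

random_state <- function() {
  x <- stats::runif(4)
  x / sum(x)
}
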