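# shared fixtures: the default synthetic acquisition and a small toy grid

acq <- flimbayes::default_acquisition()
BIN <- acq$binning
IRF <- acq$irf

# reference-dye lifetimes used throughout the validation studies (ns)
TAU_S <- 0.48
TAU_L <- 4.03
PERIOD <- 12.5

theta_ref <- function(f_S = 0.3, f_L = 0.6)
  flimbayes::decay_params(f_S, f_L, TAU_S, TAU_L, PERIOD)

# tiny 8-bin acquisition for closed-form oracles
tiny_binning <- function(n = 8, dt = 0.5) flimbayes::flim_binning(n, dt)

# synthetic masters for the mixing studies: near-pure dyes with a small
# (0.005) background fraction
make_masters <- function() {
  fb <- 0.005
  list(
    short = flimbayes::master_curve(
      flimbayes::decay_params(1 - fb, 0, TAU_S, TAU_L, PERIOD),
      IRF, BIN, label = "short-only"),
    long = flimbayes::master_curve(
      flimbayes::decay_params(0, 1 - fb, TAU_S, TAU_L, PERIOD),
      IRF, BIN, label = "long-only"))
}
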