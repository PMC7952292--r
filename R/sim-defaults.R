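# Frozen calibration constants for the synthetic-population generator.
#
# The cutpoints are the quantiles of the simulated noisy disability
# (1 - latent utility + item noise, under the default demographic model and
# noise scales latent_sd = 0.106, item_sd = 0.083) at the cumulative level
# targets of `eq5d_level_targets`; the SF-1 cutpoints are the quantiles of
# the noiseless disability at the cumulative published SF-1 distribution
# (6.2 / 25.3 / 44.2 / 20.4 / 3.9 %). The noise scales were chosen so that
# the population OLS gradient of the toy-set index on age reproduces the
# generating latent slope (discretisation gain ~ 1). Computed once by a
# deterministic n = 2e6 simulation; see the methods vignette.

default_cutpoints <- rbind(
  mobility           = c(0.178708, 0.242785, 0.304715, 0.479617),
  self_care          = c(0.278084, 0.331310, 0.400076, 0.493615),
  usual_activities   = c(0.221542, 0.295011, 0.364968, 0.480133),
  pain_discomfort    = c(0.073609, 0.189677, 0.298121, 0.492766),
  anxiety_depression = c(0.113893, 0.252467, 0.352748, 0.493335)
)

default_sf1_cutpoints <- c(-0.104539, 0.024136, 0.170708, 0.302993)
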