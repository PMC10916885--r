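# Shared trial constructors for observer-model and responder tests.

# A trial whose three maps are clean gratings at the analysis wavelength:
# the pooled differences are then the channelized circular distances between
# the map orientations.
grating_trial <- function(theta_image, theta_object, theta_probe,
                          dims = c(100L, 90L), response = NULL) {
  lambda <- 0.02 * dims[2]
  modelTrialInput(make_grating(dims, theta_image, lambda),
                  2 + make_grating(dims, theta_object, lambda),
                  make_grating(dims, theta_probe, lambda),
                  probe_point = c(dims[1] %/% 2, dims[2] %/% 2),
                  human_response = response)
}
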