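# Shared fixtures: the ensemble-mean curve, the bundled reference parameter
# sets, and small generators used across test files.

mean_curve <- function() calibration_params(245, 3271, 31.7)

ref_fixture <- function() reference_geometries()

# Noiseless dataset from known truth at the standard eight-dose schedule.
noiseless_dataset <- function(params, doses = c(16, 24, 32, 48, 64, 80, 96, 128),
                              background = params$p0, ...) {
  calibration_dataset(doses, pixel_from_dose(params, doses),
                      background = background, ...)
}

# Random valid parameter triple, broadly spanning realistic film curves.
random_params <- function() {
  calibration_params(p0 = runif(1, 150, 350),
                     ps = runif(1, 2500, 4500),
                     m = runif(1, 20, 50))
}
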