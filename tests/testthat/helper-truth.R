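# Shared truth bundles and random parameter draws used across test files.

truth_light <- function() light_params(pn_max = 46.03, aqy = 0.09,
                                        theta = 0.8, rd = 2)
truth_fvcb <- function() fvcb_params(vcmax = 105.91, jmax = 191.66, rd = 1.5)
truth_richards <- function() richards_params(a = 27, b = 25, k = 0.25,
                                             n = 1.2)

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

rand_light_params <- function() {
  light_params(pn_max = runif1(20, 60), aqy = runif1(0.03, 0.12),
               theta = runif1(0.2, 0.95), rd = runif1(0.5, 4))
}

# draws constrained so both limitation states occur on the standard ladder
rand_fvcb_params <- function() {
  vcmax <- runif1(60, 150)
  fvcb_params(vcmax = vcmax, jmax = vcmax * runif1(1.6, 2.6),
              rd = runif1(0.5, 3))
}

rand_richards_params <- function() {
  richards_params(a = runif1(15, 35), b = runif1(8, 80),
                  k = runif1(0.15, 0.45), n = runif1(0.6, 2.5))
}
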