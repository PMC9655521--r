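# Reference cross-classification used across the suite: recovered integer
# counts (42, 16, 20, 8 | 253, 127, 155, 371) for LS-BMD x TBS x fracture.
study_xt <- function() study_crosstab()

# random valid crosstab for property tests
random_xt <- function(n_d = 100, n_h = 400) {
  pd <- as.vector(stats::rmultinom(1, n_d, prob = runif(4, 0.05, 1)))
  ph <- as.vector(stats::rmultinom(1, n_h, prob = runif(4, 0.05, 1)))
  paired_crosstab(setNames(pd, c("pp", "pn", "np", "nn")),
                  setNames(ph, c("pp", "pn", "np", "nn")))
}
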