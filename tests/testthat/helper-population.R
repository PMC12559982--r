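# Shared fixtures, generated in code and memoised for the test run.

ctrl <- preset_parameters("control")
ctrl_tp <- preset_parameters("control", "transient")
ctrl_idp <- preset_parameters("control", "influx")

# moderate cohort for decomposition unit tests
pop12 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_population(
        population_spec(n_synapses = 12, noise_cv = 0.1,
                        n_repetitions = 3, seed = 42))
    cache
  }
})

# full-design cohort at the study's default size
pop50 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_population(population_spec(seed = 101))
    cache
  }
})

# mean initial quantal content over the unconditioned layers
cohort_m1 <- function(tensor) {
  lay <- dimnames(tensor)$layer
  uncond <- grep("_pre", lay, invert = TRUE)
  apply(unclass(tensor)[1, , uncond, drop = FALSE], 2, mean)
}
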