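# Shared fixture builders; everything is generated in code.

# baseline lagged parameter set used across tests
br_params <- function() {
  growth_params(n0 = 0.15, r = 0.4, k = 1.26, v = 1, q0 = 0.2, m = 0.5)
}

# noise-free single-well curve from given params
clean_curve <- function(params, times = seq(0, 35.75, by = 0.25),
                        well = "w01", strain = NULL) {
  growth_curve(
    data.frame(time = times, well = well,
               od = evaluate_growth(params, times)),
    strain = strain
  )
}

# noisy multi-well curve (no blank background; direct residual structure)
noisy_curve <- function(params, n_wells = 3, sd = 0.02, seed = 1,
                        times = seq(0, 35.75, by = 0.25)) {
  design <- plate_design(
    groups = list(list(label = "s", params = params, n_wells = n_wells)),
    duration = max(times) + times[2], interval = times[2],
    blank_wells = 0, blank_level = 0
  )
  plate_strain(generate_plate(design, noise_model(additive_sd = sd,
                                                  seed = seed)), "s")
}

# random valid lagged parameter sets for property tests
random_br_params <- function(n, seed = 1) {
  with_seed_local(seed, {
    lapply(seq_len(n), function(i) {
      n0 <- runif(1, 0.02, 0.3)
      growth_params(
        n0 = n0,
        r = runif(1, 0.1, 1.5),
        k = n0 + runif(1, 0.5, 2),
        v = exp(runif(1, log(0.3), log(3))),
        q0 = exp(runif(1, log(0.02), log(5))),
        m = runif(1, 0.1, 2)
      )
    })
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}
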