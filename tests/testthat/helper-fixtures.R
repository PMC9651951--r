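# small simulated populations shared across tests; built once per run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(generator_config(
        n_time_cells = 8, n_distractor_cells = 3, n_interneurons = 2,
        trials_per_cell = 25, seed = 99))
    }
    cache
  }
})

# fits for the parameter-recovery acceptance checks (shared by the alpha and
# width-law criteria); schedule is the documented reduced one
recovery_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(c(11L, 12L, 13L), function(s) {
        cfg <- generator_config(n_time_cells = 131, n_distractor_cells = 0,
                                n_interneurons = 0, trials_per_cell = 25,
                                seed = s)
        sim <- simulate_population(cfg)
        fit <- fit_hbm(sim$spikes, sim$delay, c(0.35, 7.2), "main",
                       control = mcmc_control(chains = 4, warmup = 1000,
                                              samples = 500, seed = s))
        list(sim = sim, fit = fit)
      })
    }
    cache
  }
})
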