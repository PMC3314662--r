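# deterministic generator settings used across tests: all random components
# off except residual noise, so closed-form expectations apply
quiet_spec <- function(n_probes = 20, noise_sd = 0, planted = numeric(0),
                       seed = 1L, n_animals = 3) {
  simulation_spec(n_probes = n_probes, n_animals = n_animals,
                  probe_sd = 0, animal_sd = 0, array_sd = 0,
                  noise_sd = noise_sd, planted_effects = planted,
                  seed = seed)
}

# time_course wrapper for hand-built readout trajectories
manual_time_course <- function(time, y, readout = "TNF") {
  structure(list(time = time,
                 concentrations = matrix(y, ncol = 1,
                                         dimnames = list(NULL, readout)),
                 readout = readout),
            class = "time_course")
}
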